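# 2-D TEM cristae analysis: thresholding, line profiles, membrane
# doublet detection, W_O / W_I / S measurement and 1/3/5 quality
# scoring.

#' Threshold cristae membranes in a TEM image
#'
#' Applies an automatic global threshold (Otsu) so that the dark cristae
#' membranes become a binary mask.
#'
#' @param image numeric matrix, grey values in `[0, 1]`.
#' @return Logical matrix, `TRUE` on membrane pixels.
#' @export
threshold_membranes <- function(image) {
  stopifnot(is.matrix(image))
  if (diff(range(image)) < 1e-8)
    stop(errorCondition("constant image: threshold undefined",
         class = c("mitomorph_degenerate_error", "error", "condition")))
  thr <- EBImage::otsu(EBImage::Image(image))
  image < thr
}

#' Grey-level profile along a line
#'
#' Samples the image by bilinear interpolation at sub-pixel steps along
#' a straight line and returns positions in nanometres.
#'
#' @param image numeric matrix.
#' @param p0,p1 line endpoints in pixel coordinates `c(x, y)`.
#' @param pixel_size_nm pixel pitch (nm).
#' @param step_px sampling step along the line (px).
#' @return Data frame of class `cristae_profile` with `pos_nm`
#'   (strictly increasing) and `value`.
#' @export
line_profile <- function(image, p0, p1, pixel_size_nm = 2,
                         step_px = 0.25) {
  d <- dim(image)
  for (p in list(p0, p1))
    if (p[1] < 1 || p[1] > d[1] || p[2] < 1 || p[2] > d[2])
      stop(errorCondition("profile line endpoint outside the image",
           class = c("mitomorph_bounds_error", "error", "condition")))
  len_px <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, floor(len_px / step_px) + 1L)
  tt <- seq(0, len_px, length.out = n)
  xs <- p0[1] + tt / len_px * (p1[1] - p0[1])
  ys <- p0[2] + tt / len_px * (p1[2] - p0[2])
  x0 <- pmin(pmax(floor(xs), 1L), d[1] - 1L)
  y0 <- pmin(pmax(floor(ys), 1L), d[2] - 1L)
  fx <- xs - x0; fy <- ys - y0
  v <- image[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    image[cbind(x0 + 1L, y0)] * fx * (1 - fy) +
    image[cbind(x0, y0 + 1L)] * (1 - fx) * fy +
    image[cbind(x0 + 1L, y0 + 1L)] * fx * fy
  structure(data.frame(pos_nm = tt * pixel_size_nm, value = v),
            class = c("cristae_profile", "data.frame"),
            pixel_size_nm = pixel_size_nm, p0 = p0, p1 = p1)
}

# local maxima of `s` with prominence; returns index, height, prominence
find_peaks <- function(s, min_prom) {
  n <- length(s)
  if (n < 3L) return(integer(0))
  cand <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n]) + 1L
  keep <- integer(0); proms <- numeric(0)
  for (p in cand) {
    lmin <- s[p]; q <- p
    while (q > 1L && s[q - 1L] <= s[p]) { q <- q - 1L
      lmin <- min(lmin, s[q]) }
    left_base <- if (q == 1L && s[q] <= s[p]) min(lmin, s[1]) else lmin
    rmin <- s[p]; q <- p
    while (q < n && s[q + 1L] <= s[p]) { q <- q + 1L
      rmin <- min(rmin, s[q]) }
    right_base <- if (q == n && s[q] <= s[p]) min(rmin, s[n]) else rmin
    prom <- s[p] - max(left_base, right_base)
    if (prom >= min_prom) { keep <- c(keep, p); proms <- c(proms, prom) }
  }
  list(idx = keep, prom = proms)
}

# linear-interpolated crossing of level `h` scanning from `from` in
# direction `dir` (+1/-1); returns a fractional index
cross_level <- function(s, from, dir, h) {
  n <- length(s)
  q <- from
  while (q + dir >= 1L && q + dir <= n) {
    if (s[q + dir] < h) {
      frac <- (s[q] - h) / (s[q] - s[q + dir])
      return(q + dir * frac)
    }
    q <- q + dir
  }
  q
}

#' Detect cristae membrane doublets in a grey profile
#'
#' Each crista appears in a TEM line profile as a doublet of dark
#' membrane peaks around a brighter lumen.  Membrane peaks are detected
#' on the inverted profile with a prominence threshold, and consecutive
#' peaks closer than `pair_gap_nm` are paired into doublets
#' (smallest gaps first).  For each doublet the outer and inner membrane
#' edges are located at half-prominence crossings; unpaired peaks are
#' flagged and excluded.
#'
#' @param profile a [line_profile()] result.
#' @param min_prominence peak prominence threshold as a fraction of the
#'   profile grey range.
#' @param pair_gap_nm maximum peak-to-peak distance within a doublet.
#' @return Data frame of class `doublets`: one row per doublet with peak
#'   and edge positions (nm).  Attribute `n_unpaired` counts flagged
#'   peaks.
#' @export
detect_doublets <- function(profile, min_prominence = 0.25,
                            pair_gap_nm = 32) {
  stopifnot(inherits(profile, "cristae_profile"))
  v <- profile$value
  pos <- profile$pos_nm
  if (length(v) < 8L)
    stop("profile too short for doublet detection")
  rng <- diff(range(v))
  empty <- structure(data.frame(peak_left_nm = numeric(0),
                                peak_right_nm = numeric(0),
                                outer_left_nm = numeric(0),
                                inner_left_nm = numeric(0),
                                inner_right_nm = numeric(0),
                                outer_right_nm = numeric(0)),
                     class = c("doublets", "data.frame"), n_unpaired = 0L)
  if (rng < 1e-8) return(empty)
  s <- max(v) - v
  pk <- find_peaks(s, min_prom = min_prominence * rng)
  if (length(pk$idx) < 2L) return(empty)
  ord <- order(pk$idx)
  idx <- pk$idx[ord]; prom <- pk$prom[ord]
  gaps <- pos[idx[-1]] - pos[idx[-length(idx)]]
  paired <- rep(FALSE, length(idx))
  pairs <- list()
  for (g in order(gaps)) {
    if (gaps[g] > pair_gap_nm) break
    if (paired[g] || paired[g + 1L]) next
    paired[c(g, g + 1L)] <- TRUE
    pairs[[length(pairs) + 1L]] <- g
  }
  if (!length(pairs)) return(empty)
  rows <- lapply(sort(unlist(pairs)), function(g) {
    iL <- idx[g]; iR <- idx[g + 1L]
    hL <- s[iL] - 0.5 * prom[g]
    hR <- s[iR] - 0.5 * prom[g + 1L]
    step <- mean(diff(pos))
    to_nm <- function(fidx) pos[1] + (fidx - 1) * step
    data.frame(peak_left_nm = pos[iL], peak_right_nm = pos[iR],
               outer_left_nm = to_nm(cross_level(s, iL, -1L, hL)),
               inner_left_nm = to_nm(cross_level(s, iL, +1L, hL)),
               inner_right_nm = to_nm(cross_level(s, iR, -1L, hR)),
               outer_right_nm = to_nm(cross_level(s, iR, +1L, hR)))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("doublets", "data.frame"),
            n_unpaired = sum(!paired))
}

#' Cristae dimensions from detected doublets
#'
#' Computes, in nanometres, the outer width `W_O` (outer-edge to
#' outer-edge), the lumen width `W_I` (inner-edge to inner-edge) and the
#' spacing `S` (gap between the facing outer edges of consecutive
#' doublets; `NA` after the last doublet).
#'
#' @param doublets a [detect_doublets()] result.
#' @return Data frame of class `cristae_dims` with columns `W_O_nm`,
#'   `W_I_nm`, `S_nm`.
#' @export
measure_dims <- function(doublets) {
  stopifnot(inherits(doublets, "doublets"))
  n <- nrow(doublets)
  if (n == 0L)
    return(structure(data.frame(W_O_nm = numeric(0), W_I_nm = numeric(0),
                                S_nm = numeric(0)),
                     class = c("cristae_dims", "data.frame")))
  W_O <- doublets$outer_right_nm - doublets$outer_left_nm
  W_I <- doublets$inner_right_nm - doublets$inner_left_nm
  S <- c(doublets$outer_left_nm[-1] - doublets$outer_right_nm[-n],
         NA_real_)
  ok <- W_I > 0 & W_O > W_I
  structure(data.frame(W_O_nm = W_O, W_I_nm = W_I, S_nm = S)[ok, ,
                                                             drop = FALSE],
            class = c("cristae_dims", "data.frame"),
            n_dropped = sum(!ok))
}

#' Cristae quality score (1 / 3 / 5)
#'
#' Scores a mitochondrion by the fraction of its area covered by ordered
#' lamellar texture: the membrane mask is filtered for elongated
#' components and the covered fraction is the share of region pixels
#' within `cover_radius_nm` of a retained membrane.  Score 1 (ordered)
#' when the coverage reaches `hi`, 5 (no discernible cristae) when it is
#' at most `lo`, else 3 (partially ordered).
#'
#' @param image numeric matrix.
#' @param region logical matrix marking the mitochondrion interior.
#' @param pixel_size_nm pixel pitch (nm).
#' @param hi,lo coverage thresholds for scores 1 and 5.
#' @param cover_radius_nm lamellar neighbourhood radius.
#' @param min_area_px minimum region size.
#' @return List of class `quality_score` with `score` and `coverage`.
#' @export
score_quality <- function(image, region, pixel_size_nm = 2, hi = 0.70,
                          lo = 0.20, cover_radius_nm = 45,
                          min_area_px = 400L) {
  if (sum(region) < min_area_px)
    stop(errorCondition("region too small for quality scoring",
         class = c("mitomorph_toosmall_error", "error", "condition")))
  mask <- threshold_membranes(image) & region
  cover <- 0
  if (any(mask)) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    ft <- EBImage::computeFeatures.moment(lab)
    ft <- as.data.frame(ft)
    min_len_px <- 3 * cover_radius_nm / pixel_size_nm
    keep_ids <- which(ft$m.majoraxis >= min_len_px &
                        ft$m.eccentricity >= 0.90)
    if (length(keep_ids)) {
      kept <- matrix(as.integer(lab) %in% keep_ids, nrow(image),
                     ncol(image))
      dm <- as.matrix(EBImage::distmap(EBImage::Image(1 - kept)))
      cover <- mean(dm[region] <= cover_radius_nm / pixel_size_nm)
    }
  }
  score <- if (cover >= hi) 1L else if (cover <= lo) 5L else 3L
  structure(list(score = score, coverage = cover),
            class = "quality_score")
}

#' @export
print.quality_score <- function(x, ...) {
  cat(sprintf("cristae quality score %d (ordered coverage %.2f)\n",
              x$score, x$coverage))
  invisible(x)
}

#' Estimate the lamella normal direction in a region
#'
#' Structure-tensor orientation estimate used to auto-orient profile
#' lines perpendicular to the local lamella direction in batch mode.
#'
#' @param image numeric matrix.
#' @param region logical matrix weighting the estimate.
#' @return Angle (radians) of the dominant gradient direction, i.e. the
#'   lamella normal.
#' @export
lamella_normal <- function(image, region) {
  sm <- ebimage_blur(image, 1.5)
  d <- dim(sm)
  gx <- matrix(0, d[1], d[2]); gy <- matrix(0, d[1], d[2])
  gx[2:(d[1] - 1), ] <- (sm[3:d[1], ] - sm[1:(d[1] - 2), ]) / 2
  gy[, 2:(d[2] - 1)] <- (sm[, 3:d[2]] - sm[, 1:(d[2] - 2)]) / 2
  w <- region
  jxx <- sum(gx[w]^2); jyy <- sum(gy[w]^2); jxy <- sum((gx * gy)[w])
  0.5 * atan2(2 * jxy, jxx - jyy)
}

#' Measure cristae dimensions on an image with an auto-oriented line
#'
#' Convenience pipeline: estimate the lamella normal, lay a profile line
#' through the region centroid, detect doublets and measure dimensions.
#'
#' @inheritParams score_quality
#' @param ... passed on to [detect_doublets()].
#' @return A `cristae_dims` data frame.
#' @export
measure_cristae_auto <- function(image, region, pixel_size_nm = 2, ...) {
  th <- lamella_normal(image, region)
  co <- which(region, arr.ind = TRUE)
  ctr <- colMeans(co)
  d <- dim(image)
  # extend the line to the region extent along the normal
  tproj <- (co[, 1] - ctr[1]) * cos(th) + (co[, 2] - ctr[2]) * sin(th)
  lo <- quantile(tproj, 0.02); hi <- quantile(tproj, 0.98)
  p0 <- pmin(pmax(ctr + lo * c(cos(th), sin(th)), 1), d)
  p1 <- pmin(pmax(ctr + hi * c(cos(th), sin(th)), 1), d)
  pr <- line_profile(image, p0, p1, pixel_size_nm)
  measure_dims(detect_doublets(pr, ...))
}
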