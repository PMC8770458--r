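#' Parameters for the synthetic TEM cristae image generator
#'
#' Describes a TEM-like 2-D greyscale image of a single mitochondrion
#' filled with parallel cristae lamellae.  Each crista is a membrane
#' doublet: two dark membrane bands whose outer edges are `W_O` apart
#' enclosing a bright lumen of width `W_I`; adjacent cristae are
#' separated by an edge-to-edge spacing `S`.  Membranes are dark on a
#' light background (TEM convention), rendered with sub-pixel
#' anti-aliasing, then mildly blurred with additive Gaussian grey noise.
#'
#' Default dimensions are the wild-type cardiac values used throughout
#' the package: outer width 36 nm, lumen 16 nm, spacing 28 nm.
#'
#' @param pixel_size_nm pixel pitch (nm).
#' @param image_px image size in pixels (x, y).
#' @param W_O_nm,W_I_nm,S_nm named `c(mean, sd)` of the outer width,
#'   lumen width and spacing (nm), drawn per crista.
#' @param n_cristae number of cristae; `NULL` fills the coverage patch,
#'   `0` draws a blank mitochondrion.
#' @param quality_class 1 (ordered), 3 (partially ordered) or 5 (no
#'   discernible cristae); sets the default ordered-lamella coverage.
#' @param coverage ordered-lamella coverage fraction of the
#'   mitochondrial extent, overriding the class default
#'   (1 -> 0.85, 3 -> 0.5, 5 -> 0).
#' @param noise_sd grey-level noise standard deviation (0--1 scale).
#' @param blur_sigma_px Gaussian blur applied after rasterization.
#' @param seed RNG seed.
#' @return An object of class `cristae_params`.
#' @export
cristae_params <- function(pixel_size_nm = 2, image_px = c(640, 640),
                           W_O_nm = c(mean = 36, sd = 2),
                           W_I_nm = c(mean = 16, sd = 1),
                           S_nm = c(mean = 28, sd = 3),
                           n_cristae = NULL, quality_class = 1L,
                           coverage = NULL, noise_sd = 0.04,
                           blur_sigma_px = 1, seed = 1L) {
  if (W_I_nm[["mean"]] >= W_O_nm[["mean"]])
    stop("W_I must be smaller than W_O")
  if (S_nm[["mean"]] <= 0) stop("S must be positive")
  if (!quality_class %in% c(1L, 3L, 5L))
    stop("quality_class must be 1, 3 or 5")
  if (is.null(coverage))
    coverage <- c(`1` = 0.85, `3` = 0.5, `5` = 0)[[as.character(quality_class)]]
  structure(list(pixel_size_nm = pixel_size_nm,
                 image_px = as.integer(image_px),
                 W_O_nm = W_O_nm, W_I_nm = W_I_nm, S_nm = S_nm,
                 n_cristae = n_cristae,
                 quality_class = as.integer(quality_class),
                 coverage = coverage, noise_sd = noise_sd,
                 blur_sigma_px = blur_sigma_px, seed = seed),
            class = "cristae_params")
}

# half-chord length (px) of the scaled ellipse rho at offset t (px)
# perpendicular to the lamella normal at angle phi
ellipse_chord <- function(t, a, b, phi, rho = 1) {
  cphi <- cos(phi); sphi <- sin(phi)
  al <- (sphi / a)^2 + (cphi / b)^2
  be <- 2 * t * cphi * sphi * (1 / b^2 - 1 / a^2)
  ga <- (cphi / a)^2 + (sphi / b)^2
  disc <- be^2 - 4 * al * (ga * t^2 - rho^2)
  ifelse(disc > 0, sqrt(disc) / al, 0)
}

#' Generate a synthetic TEM cristae image with ground truth
#'
#' @param params a [cristae_params()].
#' @return A list of class `cristae_phantom`: `image` (numeric matrix,
#'   0--1 grey), and `truth` containing the pre-noise membrane and
#'   cristae masks, the mitochondrion interior mask, the lamella
#'   orientation, a suggested profile line along the lamella normal, a
#'   per-crista table of true positions and dimensions, the realized
#'   coverage fraction, and the analytic membrane trace length per
#'   mitochondrial area (`b_a_per_nm`).
#' @examples
#' ph <- simulate_cristae_image(cristae_params(seed = 3))
#' nrow(ph$truth$cristae)
#' @export
simulate_cristae_image <- function(params = cristae_params()) {
  stopifnot(inherits(params, "cristae_params"))
  set.seed(params$seed)
  d <- params$image_px
  px <- params$pixel_size_nm
  cx <- d[1] / 2; cy <- d[2] / 2
  a <- 0.44 * d[1] * runif(1, 0.9, 1.0)
  b <- 0.40 * d[2] * runif(1, 0.9, 1.0)
  phi <- runif(1, 0, pi)            # lamella normal direction
  xg <- matrix(seq_len(d[1]) - cx, d[1], d[2])
  yg <- matrix(rep(seq_len(d[2]) - cy, each = d[1]), d[1], d[2])
  metric <- sqrt((xg / a)^2 + (yg / b)^2)
  interior <- metric <= 1
  ring_w_px <- 7 / px
  ring <- metric <= 1 & metric >= 1 - ring_w_px / min(a, b)

  bg <- 0.82; interior_grey <- 0.75; dark <- 0.25
  img <- matrix(bg, d[1], d[2])
  img[interior] <- interior_grey
  img[ring] <- dark

  tcoord <- xg * cos(phi) + yg * sin(phi)       # px along lamella normal
  h_t <- sqrt((a * cos(phi))^2 + (b * sin(phi))^2)
  rho_in <- 0.92                                 # lamellae kept off the ring
  inner <- metric <= rho_in

  pitch_px <- (params$W_O_nm[["mean"]] + params$S_nm[["mean"]]) / px
  n_cr <- params$n_cristae
  if (is.null(n_cr))
    n_cr <- max(0L, floor(params$coverage * 2 * h_t * rho_in / pitch_px))
  cr <- data.frame(centre_t_nm = numeric(0), W_O_nm = numeric(0),
                   W_I_nm = numeric(0), S_to_next_nm = numeric(0))
  cristae_alpha <- matrix(0, d[1], d[2])
  b_len_px <- 0
  if (n_cr > 0) {
    wo <- pmax(params$W_I_nm[["mean"]] + 6,
               rnorm(n_cr, params$W_O_nm[["mean"]], params$W_O_nm[["sd"]]))
    wi <- pmin(wo - 4, pmax(4, rnorm(n_cr, params$W_I_nm[["mean"]],
                                     params$W_I_nm[["sd"]])))
    ss <- pmax(6, rnorm(max(n_cr - 1, 0), params$S_nm[["mean"]],
                        params$S_nm[["sd"]]))
    centres <- numeric(n_cr)
    if (n_cr > 1) {
      for (q in 2:n_cr)
        centres[q] <- centres[q - 1] + wo[q - 1] / 2 + ss[q - 1] + wo[q] / 2
    }
    centres <- centres - mean(centres)           # nm, centred on the mito
    aa <- 1                                      # anti-alias width (px)
    for (q in seq_len(n_cr)) {
      u <- tcoord * px - centres[q]              # nm in the crista frame
      for (side in c(-1, 1)) {
        lo <- if (side < 0) -wo[q] / 2 else wi[q] / 2
        hi <- if (side < 0) -wi[q] / 2 else wo[q] / 2
        pen <- pmin(u - lo, hi - u) / px         # signed distance, px
        alpha <- pmin(pmax(pen / aa + 0.5, 0), 1)
        alpha[!inner] <- 0
        cristae_alpha <- pmax(cristae_alpha, alpha)
        # analytic membrane centreline length (two leaflets drawn as one
        # band; centreline at the band middle)
        mid_nm <- (lo + hi) / 2 + centres[q]
        b_len_px <- b_len_px + ellipse_chord(mid_nm / px, a, b, phi,
                                             rho_in)
      }
    }
    img <- img * (1 - cristae_alpha) + dark * cristae_alpha
    s_next <- c(if (n_cr > 1) ss else numeric(0), NA_real_)
    cr <- data.frame(centre_t_nm = centres, W_O_nm = wo, W_I_nm = wi,
                     S_to_next_nm = s_next)
  }

  cristae_mask <- cristae_alpha >= 0.5
  membrane_mask <- cristae_mask | ring
  mito_area_nm2 <- sum(inner) * px^2
  b_a <- (b_len_px * px) / mito_area_nm2        # membrane length per area

  # profile line along the lamella normal through the mito centre
  half_line <- 0.95 * h_t * rho_in
  p0 <- c(cx - half_line * cos(phi), cy - half_line * sin(phi))
  p1 <- c(cx + half_line * cos(phi), cy + half_line * sin(phi))

  clean <- img
  if (params$blur_sigma_px > 0)
    img <- ebimage_blur(img, params$blur_sigma_px)
  if (params$noise_sd > 0)
    img <- img + matrix(rnorm(length(img), 0, params$noise_sd),
                        d[1], d[2])
  img <- pmin(pmax(img, 0), 1)

  truth <- list(orientation = phi, interior_mask = interior,
                inner_mask = inner, membrane_mask = membrane_mask,
                cristae_mask = cristae_mask, cristae = cr,
                profile_line = list(p0 = p0, p1 = p1),
                coverage = if (h_t > 0 && n_cr > 0)
                  n_cr * pitch_px / (2 * h_t * rho_in) else 0,
                b_a_per_nm = b_a, pixel_size_nm = px,
                clean_image = clean,
                params = unclass(params))
  structure(list(image = img, truth = truth), class = "cristae_phantom")
}

ebimage_blur <- function(img, sigma_px) {
  as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma_px))
}

#' @export
print.cristae_phantom <- function(x, ...) {
  cat(sprintf("cristae_phantom: %d x %d px, %d cristae, quality class %d\n",
              nrow(x$image), ncol(x$image), nrow(x$truth$cristae),
              x$truth$params$quality_class))
  invisible(x)
}
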