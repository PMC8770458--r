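#' Labelled 3-D volume of segmented mitochondria
#'
#' The unit of all 3-D analysis: an integer raster in which 0 is
#' background and each positive integer is one segmented mitochondrion,
#' together with binary nucleus / sarcolemma masks, an optional
#' cardiomyocyte mask, and the voxel geometry.
#'
#' @param raster integer 3-D array; 0 = background, >0 = mitochondrion id.
#' @param geom a [voxel_geometry()] matching `dim(raster)`.
#' @param nucleus_mask,sarcolemma_mask logical arrays with the raster's
#'   dimensions (or `NULL` when absent).  Must be disjoint from
#'   mitochondrion voxels.
#' @param cm_mask logical array marking the cardiomyocyte (reference
#'   space for stereology).  Defaults to everything.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(raster, geom, nucleus_mask = NULL,
                         sarcolemma_mask = NULL, cm_mask = NULL) {
  if (!is.array(raster) || length(dim(raster)) != 3L)
    stop("`raster` must be a 3-D array")
  storage.mode(raster) <- "integer"
  if (!inherits(geom, "voxel_geometry"))
    stop("`geom` must be a voxel_geometry")
  if (!identical(dim(raster), as.integer(geom$dims)))
    stop("raster dimensions do not match `geom$dims`")
  for (nm in c("nucleus_mask", "sarcolemma_mask", "cm_mask")) {
    m <- get(nm)
    if (!is.null(m)) {
      if (!identical(dim(m), dim(raster)))
        stop(sprintf("`%s` dimensions do not match the raster", nm))
      if (nm != "cm_mask" && any(m & raster > 0L))
        stop(sprintf("`%s` overlaps mitochondrion voxels", nm))
    }
  }
  structure(list(raster = raster, geom = geom,
                 nucleus_mask = nucleus_mask,
                 sarcolemma_mask = sarcolemma_mask,
                 cm_mask = cm_mask),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  labs <- volume_labels(x)
  cat("label_volume\n")
  print(x$geom)
  cat(sprintf("  %d labelled mitochondria; masks: nucleus=%s sarcolemma=%s cm=%s\n",
              length(labs),
              !is.null(x$nucleus_mask), !is.null(x$sarcolemma_mask),
              !is.null(x$cm_mask)))
  invisible(x)
}

#' Label ids present in a volume
#'
#' @param volume a [label_volume()].
#' @return Sorted integer vector of positive label ids.
#' @export
volume_labels <- function(volume) {
  stopifnot(inherits(volume, "label_volume"))
  r <- volume$raster
  mx <- max(r)
  if (mx < 1L) return(integer(0))
  which(tabulate(r, nbins = mx) > 0L)
}

# one-pass per-label voxel counts and bounding boxes
label_info <- function(volume) {
  r <- volume$raster
  idx <- which(r > 0L)
  if (length(idx) == 0L)
    return(data.frame(label = integer(0), n_vox = integer(0),
                      i0 = integer(0), i1 = integer(0), j0 = integer(0),
                      j1 = integer(0), k0 = integer(0), k1 = integer(0)))
  d <- dim(r)
  i <- (idx - 1L) %% d[1] + 1L
  j <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
  k <- (idx - 1L) %/% (d[1] * d[2]) + 1L
  dt <- data.table::data.table(lab = r[idx], i = i, j = j, k = k)
  agg <- dt[, list(n_vox = .N, i0 = min(i), i1 = max(i), j0 = min(j),
                   j1 = max(j), k0 = min(k), k1 = max(k)), by = "lab"]
  data.table::setorderv(agg, "lab")
  out <- as.data.frame(agg)
  names(out)[1] <- "label"
  out
}

# crop a padded bounding box; returns list with the sub-arrays and offsets
crop_box <- function(volume, box, pad = 2L) {
  d <- dim(volume$raster)
  i0 <- max(1L, box$i0 - pad); i1 <- min(d[1], box$i1 + pad)
  j0 <- max(1L, box$j0 - pad); j1 <- min(d[2], box$j1 + pad)
  k0 <- max(1L, box$k0 - pad); k1 <- min(d[3], box$k1 + pad)
  list(raster = volume$raster[i0:i1, j0:j1, k0:k1, drop = FALSE],
       nucleus = if (!is.null(volume$nucleus_mask))
         volume$nucleus_mask[i0:i1, j0:j1, k0:k1, drop = FALSE],
       sarcolemma = if (!is.null(volume$sarcolemma_mask))
         volume$sarcolemma_mask[i0:i1, j0:j1, k0:k1, drop = FALSE],
       origin = c(i0, j0, k0))
}
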