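# Lossless fixture I/O: multi-page 16-bit TIFF label stacks with a JSON
# sidecar for voxel geometry, masks and ground truth.

#' Write a fixture to disk
#'
#' Serializes a [label_volume()] (multi-page unsigned 16-bit TIFF plus
#' companion mask TIFFs and a JSON sidecar with the voxel geometry) or a
#' cristae phantom / grey image (single-page TIFF plus sidecar).  Ground
#' truth, when attached, goes into the sidecar keyed by label id so the
#' round trip is lossless.
#'
#' @param x a `label_volume`, `mito_phantom`, `cristae_phantom`, or
#'   numeric matrix.
#' @param path output path prefix (no extension).
#' @return Invisibly, the sidecar path.
#' @export
write_fixture <- function(x, path) UseMethod("write_fixture")

tiff_pages <- function(arr, scale) {
  lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] / scale)
}

#' @export
write_fixture.label_volume <- function(x, path) {
  mx <- max(x$raster)
  if (mx > 65535L) stop("more than 65535 labels cannot be stored in 16 bit")
  tiff::writeTIFF(tiff_pages(x$raster, 65535), paste0(path, "_labels.tif"),
                  bits.per.sample = 16L, compression = "none")
  masks <- list()
  for (nm in c("nucleus_mask", "sarcolemma_mask", "cm_mask")) {
    if (!is.null(x[[nm]])) {
      fn <- paste0(path, "_", sub("_mask", "", nm), ".tif")
      tiff::writeTIFF(tiff_pages(x[[nm]] * 1L, 1), fn,
                      bits.per.sample = 8L, compression = "none")
      masks[[nm]] <- basename(fn)
    }
  }
  sidecar <- list(kind = "label_volume",
                  dims = x$geom$dims, size_nm = x$geom$size_nm,
                  labels = basename(paste0(path, "_labels.tif")),
                  masks = masks,
                  package = "mitomorph")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paste0(path, ".json"))
}

#' @export
write_fixture.mito_phantom <- function(x, path) {
  write_fixture(x$volume, path)
  write_ground_truth(x$truth, paste0(path, "_truth.json"))
  invisible(paste0(path, ".json"))
}

#' @export
write_fixture.cristae_phantom <- function(x, path) {
  tiff::writeTIFF(x$image, paste0(path, ".tif"), bits.per.sample = 16L,
                  compression = "none")
  sidecar <- list(kind = "cristae_image",
                  dims = dim(x$image),
                  pixel_size_nm = x$truth$pixel_size_nm,
                  package = "mitomorph")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paste0(path, ".json"))
}

#' @export
write_fixture.matrix <- function(x, path) {
  tiff::writeTIFF(x, paste0(path, ".tif"), bits.per.sample = 16L,
                  compression = "none")
  sidecar <- list(kind = "grey_image", dims = dim(x),
                  package = "mitomorph")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paste0(path, ".json"))
}

#' Read a fixture written by [write_fixture()]
#'
#' @param path the path prefix used when writing.
#' @return The reconstructed object (`label_volume` or numeric matrix).
#' @export
read_fixture <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    stop(errorCondition(sprintf("missing sidecar %s", sidecar_path),
         class = c("mitomorph_parse_error", "error", "condition")))
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(sc$kind))
    stop(errorCondition("malformed sidecar: missing field `kind`",
         class = c("mitomorph_parse_error", "error", "condition")))
  if (sc$kind == "label_volume") {
    for (f in c("dims", "size_nm", "labels"))
      if (is.null(sc[[f]]))
        stop(errorCondition(
          sprintf("malformed sidecar: missing field `%s`", f),
          class = c("mitomorph_parse_error", "error", "condition")))
    dirn <- dirname(path)
    pages <- tiff::readTIFF(file.path(dirn, sc$labels), all = TRUE)
    raster <- array(0L, dim = sc$dims)
    for (k in seq_along(pages))
      raster[, , k] <- as.integer(round(pages[[k]] * 65535))
    read_mask <- function(nm) {
      if (is.null(sc$masks[[nm]])) return(NULL)
      pg <- tiff::readTIFF(file.path(dirn, sc$masks[[nm]]), all = TRUE)
      m <- array(FALSE, dim = sc$dims)
      for (k in seq_along(pg)) m[, , k] <- pg[[k]] > 0.5
      m
    }
    label_volume(raster, voxel_geometry(sc$dims, sc$size_nm),
                 nucleus_mask = read_mask("nucleus_mask"),
                 sarcolemma_mask = read_mask("sarcolemma_mask"),
                 cm_mask = read_mask("cm_mask"))
  } else if (sc$kind %in% c("cristae_image", "grey_image")) {
    img <- tiff::readTIFF(paste0(path, ".tif"))
    if (!is.null(sc$dims) && !identical(dim(img), as.integer(sc$dims)))
      stop(errorCondition("malformed sidecar: field `dims` mismatch",
           class = c("mitomorph_parse_error", "error", "condition")))
    img
  } else {
    stop(errorCondition(
      sprintf("malformed sidecar: unknown kind `%s`", sc$kind),
      class = c("mitomorph_parse_error", "error", "condition")))
  }
}

#' Serialize ground truth to JSON
#'
#' @param truth a `ground_truth` object.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  payload <- list(objects = truth$objects,
                  projections = truth$projections,
                  nanotunnels = truth$nanotunnels,
                  true_fraction = truth$true_fraction,
                  subtype_share = as.list(truth$subtype_share),
                  mito_vox = truth$mito_vox, cm_vox = truth$cm_vox)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read ground truth written by [write_ground_truth()]
#'
#' @param path JSON file path.
#' @return A `ground_truth`-like list.
#' @export
read_ground_truth <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(out, class = "ground_truth")
}
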