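# Digital phantoms built independently of the package's rasterizers, so
# they can serve as oracles for the measurement code.

digital_ball <- function(r, size_nm = c(1, 1, 1), pad = 4L) {
  n <- 2L * r + 2L * pad
  xs <- seq_len(n) - (n + 1) / 2
  inside <- outer(outer(xs^2, xs^2, "+"), xs^2, "+") <= r^2
  raster <- array(0L, dim = c(n, n, n))
  raster[inside] <- 1L
  label_volume(raster, voxel_geometry(c(n, n, n), size_nm))
}

digital_cube <- function(side, size_nm = c(1, 1, 1), pad = 5L) {
  n <- side + 2L * pad
  raster <- array(0L, dim = c(n, n, n))
  idx <- (pad + 1L):(pad + side)
  raster[idx, idx, idx] <- 1L
  label_volume(raster, voxel_geometry(c(n, n, n), size_nm))
}

# small-volume generator conditions used across tests
test_geom <- function(dims = c(96, 96, 20), size_nm = c(42, 42, 420)) {
  voxel_geometry(dims, size_nm)
}

# exact voxel fraction of the sampled regions (the estimand of the
# three-box protocol)
regional_fraction <- function(volume, regions = default_regions(volume$geom)) {
  mean(vapply(regions, function(rg) {
    sub <- volume$raster[rg$xlim[1]:rg$xlim[2], rg$ylim[1]:rg$ylim[2],
                         rg$zlim[1]:rg$zlim[2]]
    subcm <- volume$cm_mask[rg$xlim[1]:rg$xlim[2], rg$ylim[1]:rg$ylim[2],
                            rg$zlim[1]:rg$zlim[2]]
    100 * sum(sub > 0L) / sum(subcm)
  }, numeric(1)))
}
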