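test_that("the volume-fraction formula layer is exact on integer counts", {
  cnt <- structure(data.frame(region = 1L, n_slices = 3L, red_cm = 200L,
                              green_mito = 100L),
                   class = c("point_counts", "data.frame"))
  g <- grid_spec()
  vv <- volume_fraction(cnt, g)
  expect_equal(vv$per_region,
               100 * (100 * g$green_area_nm2) / (200 * g$red_area_nm2))
  expect_equal(round(vv$per_region, 1), 10.0)
  cnt$green_mito <- 0L
  expect_equal(volume_fraction(cnt, g)$per_region, 0)
  cnt$red_cm <- 0L
  expect_error(volume_fraction(cnt, g),
               class = "mitomorph_undefined_error")
})

test_that("empty rasters give zero mitochondrial points", {
  geom <- test_geom(c(64, 64, 12))
  v <- label_volume(array(0L, dim = geom$dims), geom,
                    cm_mask = array(TRUE, dim = geom$dims))
  g <- grid_spec(red_area_nm2 = 1e6, green_area_nm2 = 0.5e6,
                 slice_interval = 2)
  cnt <- count_points(v, g, seed = 1)
  expect_equal(sum(cnt$green_mito), 0)
  expect_gt(sum(cnt$red_cm), 0)
})

test_that("a volume that is all mitochondrion measures 100 %", {
  geom <- test_geom(c(64, 64, 12))
  v <- label_volume(array(1L, dim = geom$dims), geom,
                    cm_mask = array(TRUE, dim = geom$dims))
  g <- grid_spec(red_area_nm2 = 1e6, green_area_nm2 = 1e6,
                 slice_interval = 2, placement = "fixed")
  vv <- volume_fraction(count_points(v, g), g)
  expect_equal(vv$mean, 100)
})

test_that("point counting is unbiased against the regional voxel oracle", {
  ph <- simulate_cardiomyocyte(
    volume_params(target_mito_fraction = 0.25, seed = 4),
    test_geom(c(128, 128, 24), c(84, 84, 420)))
  oracle <- regional_fraction(ph$volume)
  g <- grid_spec(red_area_nm2 = 0.3e6, green_area_nm2 = 0.06e6,
                 slice_interval = 2)
  ests <- vapply(1:200, function(s)
    volume_fraction(count_points(ph$volume, g, seed = s), g)$mean,
    numeric(1))
  expect_lt(abs(mean(ests) - oracle), 0.5)
  # the spread shrinks roughly like 1/sqrt(points counted); fix the
  # slice pattern so lattice noise is the only variance source
  g_dense <- grid_spec(red_area_nm2 = 0.3e6, green_area_nm2 = 0.06e6,
                       slice_interval = 1)
  g_sparse <- grid_spec(red_area_nm2 = 1.2e6, green_area_nm2 = 0.24e6,
                        slice_interval = 1)
  e1 <- vapply(1:150, function(s)
    volume_fraction(count_points(ph$volume, g_dense, seed = s),
                    g_dense)$mean, numeric(1))
  e2 <- vapply(1:150, function(s)
    volume_fraction(count_points(ph$volume, g_sparse, seed = s),
                    g_sparse)$mean, numeric(1))
  expect_gt(sd(e2) / sd(e1), 1.3)
})

test_that("the edge-exclusion rule never increases a count", {
  ph <- simulate_cardiomyocyte(
    volume_params(target_mito_fraction = 0.2, seed = 8),
    test_geom(c(96, 96, 20), c(63, 63, 420)))
  g_off <- grid_spec(green_area_nm2 = 0.1e6, slice_interval = 2,
                     edge_exclusion = FALSE)
  g_on <- grid_spec(green_area_nm2 = 0.1e6, slice_interval = 2,
                    edge_exclusion = TRUE)
  for (s in 1:10) {
    a <- count_points(ph$volume, g_off, seed = s)
    b <- count_points(ph$volume, g_on, seed = s)
    expect_true(all(b$green_mito <= a$green_mito))
  }
})

test_that("regions outside the volume raise bounds errors", {
  geom <- test_geom(c(32, 32, 8))
  v <- label_volume(array(0L, dim = geom$dims), geom)
  bad <- list(list(xlim = c(1L, 64L), ylim = c(1L, 16L),
                   zlim = c(1L, 4L)))
  expect_error(count_points(v, grid_spec(), regions = bad),
               class = "mitomorph_bounds_error")
})

test_that("subpopulation shares follow the subtype tallies", {
  geom <- test_geom(c(64, 64, 12))
  r <- array(0L, dim = geom$dims); r[20:40, 20:40, ] <- 1L
  v <- label_volume(r, geom, cm_mask = array(TRUE, dim = geom$dims))
  g <- grid_spec(green_area_nm2 = 0.1e6, slice_interval = 2)
  cnt <- count_points(v, g, subtypes = c(`1` = "IFM"), seed = 2)
  sh <- subpopulation_fractions(cnt)
  expect_equal(unname(sh), c(0, 100, 0))
  cnt0 <- count_points(label_volume(array(0L, dim = geom$dims), geom),
                       g, subtypes = c(`1` = "IFM"), seed = 2)
  expect_error(subpopulation_fractions(cnt0),
               class = "mitomorph_undefined_error")
})

test_that("subpopulation recovery matches the generator shares", {
  ph <- simulate_cardiomyocyte(
    volume_params(target_mito_fraction = 0.28, seed = 21),
    test_geom(c(128, 128, 24)))
  st <- assign_subtypes(ph$volume)
  g <- grid_spec(green_area_nm2 = 0.1e6, slice_interval = 2)
  acc <- NULL
  for (s in 1:15) {
    cnt <- count_points(ph$volume, g, subtypes = st, seed = 400 + s)
    acc <- if (is.null(acc)) cnt else {
      for (cc in c("green_SSM", "green_IFM", "green_PNM"))
        acc[[cc]] <- acc[[cc]] + cnt[[cc]]
      acc
    }
  }
  sh <- subpopulation_fractions(acc)
  expect_lt(abs(sh[["IFM"]] - 100 * ph$truth$subtype_share[["IFM"]]), 5)
})

test_that("cristae surface density matches the analytic phantom", {
  ph <- simulate_cristae_image(cristae_params(seed = 9))
  tr <- ph$truth
  g <- grid_spec(sv_tile_nm = 120, sv_line_frac = 0.6)
  svs <- vapply(1:40, function(s)
    cristae_surface_density(tr$cristae_mask, tr$inner_mask, g,
                            pixel_size_nm = 2, seed = s)$sv_per_nm,
    numeric(1))
  oracle <- (4 / pi) * tr$b_a_per_nm
  expect_lt(abs(mean(svs) / oracle - 1), 0.10)
})

test_that("doubling the lamellar density doubles the estimate", {
  g <- grid_spec(sv_tile_nm = 120, sv_line_frac = 0.6)
  sv_of <- function(ph) mean(vapply(1:30, function(s)
    cristae_surface_density(ph$truth$cristae_mask, ph$truth$inner_mask,
                            g, 2, seed = s)$sv_per_nm, numeric(1)))
  ph1 <- simulate_cristae_image(cristae_params(seed = 9))
  ph2 <- simulate_cristae_image(cristae_params(S_nm = c(mean = 6, sd = 1),
                                               seed = 9))
  truth_ratio <- ph2$truth$b_a_per_nm / ph1$truth$b_a_per_nm
  expect_lt(abs((sv_of(ph2) / sv_of(ph1)) / truth_ratio - 1), 0.10)
})

test_that("no intersections means zero surface density", {
  blank <- matrix(FALSE, 64, 64)
  mito <- matrix(TRUE, 64, 64)
  sv <- cristae_surface_density(blank, mito, grid_spec(), 2, seed = 1)
  expect_equal(sv$sv_per_nm, 0)
  expect_error(cristae_surface_density(blank, matrix(FALSE, 64, 64),
                                       grid_spec(), 2, seed = 1),
               class = "mitomorph_undefined_error")
})

test_that("the circle probe converges to the trace-length density", {
  # circle of radius r inside a disc reference: trace length per area
  # 2 pi r / (pi R^2), the 2-D analogue of the sphere surface relation
  n <- 400; r <- 120; R <- 170
  xg <- matrix(seq_len(n) - n / 2, n, n)
  yg <- t(xg)
  rad <- sqrt(xg^2 + yg^2)
  band <- abs(rad - r) <= 1.5
  disc <- rad <= R
  b_a <- (2 * pi * r) / (pi * R^2)          # px per px^2
  g <- grid_spec(sv_tile_nm = 40, sv_line_frac = 0.8)
  svs <- vapply(1:30, function(s)
    cristae_surface_density(band, disc, g, pixel_size_nm = 1,
                            seed = s)$sv_per_nm, numeric(1))
  expect_lt(abs(mean(svs) / ((4 / pi) * b_a) - 1), 0.10)
})
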