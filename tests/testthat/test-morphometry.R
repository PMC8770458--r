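test_that("volume measurement is exact voxel arithmetic", {
  r <- array(0L, c(4, 4, 4)); r[2, 2, 2] <- 1L
  v <- label_volume(r, voxel_geometry(c(4, 4, 4)))
  expect_equal(measure_volume(v, 1L), 13.5 * 13.5 * 50)
  # digital ball: voxel count within 2 % of the continuum volume
  ball <- digital_ball(20)
  expect_lt(abs(measure_volume(ball, 1L) / ((4 / 3) * pi * 20^3) - 1),
            0.02)
  # magnitude check: full-size mitochondrion volumes do not overflow
  big <- simulate_mitochondrion(7.23e8, "oval", seed = 1)
  expect_gt(measure_volume(big$volume, 1L), 5e8)
  expect_error(measure_volume(v, 99L), class = "mitomorph_notfound_error")
})

test_that("surface area meets the analytic contracts", {
  ball <- digital_ball(20)
  expect_lt(abs(measure_surface_area(ball, 1L) / (4 * pi * 20^2) - 1),
            0.05)
  cube <- digital_cube(30)
  expect_lt(abs(measure_surface_area(cube, 1L) / (6 * 30^2) - 1), 0.05)
  r <- array(0L, c(6, 6, 6))
  v <- label_volume(r, voxel_geometry(c(6, 6, 6)))
  expect_error(measure_surface_area(v, 1L),
               class = "mitomorph_notfound_error")
  r[3, 3, 3] <- 1L
  v1 <- label_volume(r, voxel_geometry(c(6, 6, 6), c(1, 1, 1)))
  expect_warning(a <- measure_surface_area(v1, 1L), "single voxel")
  expect_equal(a, 6)
})

test_that("SA/Vol approaches 3/r for digital balls", {
  for (r in c(15, 20, 26)) {
    ball <- digital_ball(r)
    ratio <- measure_surface_area(ball, 1L) / measure_volume(ball, 1L)
    expect_lt(abs(ratio / (3 / r) - 1), 0.07)
  }
})

test_that("per-label volumes conserve the total labelled volume", {
  ph <- simulate_cardiomyocyte(
    volume_params(target_mito_fraction = 0.18, seed = 6),
    test_geom(c(72, 72, 16), c(84, 84, 420)))
  v <- ph$volume
  total <- sum(vapply(volume_labels(v), function(l) measure_volume(v, l),
                      numeric(1)))
  expect_equal(total, sum(v$raster > 0L) * prod(v$geom$size_nm))
})

test_that("scaling the voxel size scales volumes by k^3 and areas by k^2", {
  ball1 <- digital_ball(16)
  ball3 <- digital_ball(16, size_nm = c(3, 3, 3))
  expect_equal(measure_volume(ball3, 1L) / measure_volume(ball1, 1L), 27)
  expect_lt(abs(measure_surface_area(ball3, 1L) /
                  measure_surface_area(ball1, 1L) - 9) / 9, 0.01)
})

test_that("subtype assignment follows the contact and exclusion rules", {
  d <- c(30, 30, 8)
  r <- array(0L, dim = d)
  nuc <- array(FALSE, dim = d); sarc <- array(FALSE, dim = d)
  sarc[1:2, , ] <- TRUE
  nuc[6:10, 18:24, 3:6] <- TRUE
  r[4:6, 5:8, 3:5] <- 1L          # one-voxel gap from the sarcolemma
  r[14:17, 14:17, 3:5] <- 2L      # interior
  r[3:5, 18:25, 3:5] <- 3L        # touches both structures
  v <- label_volume(r, voxel_geometry(d), nucleus_mask = nuc,
                    sarcolemma_mask = sarc)
  expect_equal(assign_subtype(v, 1L), "SSM")
  expect_equal(assign_subtype(v, 2L), "IFM")
  expect_equal(assign_subtype(v, 3L), "excluded")
  v2 <- label_volume(r, voxel_geometry(d))
  expect_error(assign_subtype(v2, 1L), class = "mitomorph_config_error")
})

test_that("subtype assignment recovers the generator ground truth", {
  ph <- simulate_cardiomyocyte(
    volume_params(target_mito_fraction = 0.25, seed = 11),
    test_geom(c(128, 128, 24)))
  st <- assign_subtypes(ph$volume)
  tr <- setNames(ph$truth$objects$subtype, ph$truth$objects$label)
  expect_gte(mean(st[names(tr)] == tr), 0.95)
})

test_that("shape classification separates the generator classes", {
  # a perfect digital ellipsoid is oval
  sm <- simulate_mitochondrion(5e8, "oval", amplitude = 0, seed = 2)
  expect_equal(classify_shape(sm$volume, 1L), "oval")
  # population agreement at the default perturbation amplitudes
  res <- vapply(1:40, function(i) {
    cls <- if (i %% 2 == 0) "irregular" else "oval"
    sm <- simulate_mitochondrion(7.29e8, cls, seed = 4000 + i)
    classify_shape(sm$volume, 1L) == cls
  }, logical(1))
  expect_gte(mean(res), 0.90)
  # too-small objects are refused
  tiny <- array(0L, c(6, 6, 6)); tiny[3:4, 3:4, 3] <- 1L
  vt <- label_volume(tiny, voxel_geometry(c(6, 6, 6)))
  expect_error(classify_shape(vt, 1L), class = "mitomorph_toosmall_error")
})

test_that("classification degrades monotonically towards the class boundary", {
  oval_rate <- function(amp) {
    mean(vapply(1:12, function(i) {
      sm <- simulate_mitochondrion(7.29e8, "irregular", amplitude = amp,
                                   seed = 6000 + i)
      classify_shape(sm$volume, 1L) == "oval"
    }, logical(1)))
  }
  rates <- vapply(c(0.06, 0.14, 0.25), oval_rate, numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_gt(rates[1], rates[3])
})

test_that("the morphometry table is one row per non-excluded label", {
  geom <- test_geom(c(16, 16, 6))
  empty <- label_volume(array(0L, dim = geom$dims), geom)
  expect_equal(nrow(morphometry_table(empty)), 0)
  ph <- simulate_cardiomyocyte(
    volume_params(target_mito_fraction = 0.18, seed = 13),
    test_geom(c(96, 96, 20), c(63, 63, 420)))
  tab <- morphometry_table(ph$volume, projections = FALSE)
  st <- assign_subtypes(ph$volume)
  expect_equal(nrow(tab), sum(st != "excluded"))
  expect_equal(tab$sa_over_vol_per_nm,
               tab$surface_area_nm2 / tab$volume_nm3)
  # mean recovered volume per subtype within 10 % of generator truth
  tr <- ph$truth$objects
  for (s in c("SSM", "IFM")) {
    got <- mean(tab$volume_nm3[tab$subtype == s])
    want <- mean(tr$volume_nm3[tr$subtype == s])
    if (is.finite(got) && is.finite(want))
      expect_lt(abs(got / want - 1), 0.10)
  }
})
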