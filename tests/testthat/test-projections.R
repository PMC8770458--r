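test_that("a plain ellipsoid has no projections", {
  sm <- simulate_mitochondrion(7.29e8, "oval", amplitude = 0, seed = 3)
  expect_equal(nrow(detect_projections(sm$volume, 1L)), 0)
})

test_that("a capsule appendage is recovered within tolerance", {
  hits <- 0; len_err <- c(); tip_err <- c()
  for (i in 1:8) {
    sm <- simulate_mitochondrion(
      7.29e8, "oval",
      projection = list(length_um = 0.60, tipwidth_um = 0.22),
      seed = 2100 + i)
    pr <- detect_projections(sm$volume, 1L)
    if (nrow(pr) == 1L) {
      hits <- hits + 1
      len_err <- c(len_err, pr$length_um / 0.60 - 1)
      tip_err <- c(tip_err, pr$tip_width_um / 0.22 - 1)
    }
  }
  expect_gte(hits, 7)
  expect_lt(abs(mean(len_err)), 0.10)
  expect_lt(abs(mean(tip_err)), 0.20)
})

test_that("mean projection length is recovered across a size span", {
  set.seed(31)
  lens <- runif(50, 0.3, 1.0)
  got <- vapply(seq_along(lens), function(i) {
    sm <- simulate_mitochondrion(
      7.29e8, "oval",
      projection = list(length_um = lens[i], tipwidth_um = 0.22),
      seed = 5100 + i)
    pr <- detect_projections(sm$volume, 1L)
    if (nrow(pr) == 1L) pr$length_um else NA_real_
  }, numeric(1))
  ok <- !is.na(got)
  expect_gte(sum(ok), 45)
  expect_lt(abs(mean(got[ok]) / mean(lens[ok]) - 1), 0.10)
})

test_that("two disjoint ellipsoids are not a nanotunnel", {
  d <- c(60, 60, 24)
  r <- array(0L, dim = d)
  xs <- seq_len(60); zs <- seq_len(24)
  b1 <- outer(outer((xs - 18)^2 / 100, (xs - 30)^2 / 100, "+"),
              (zs - 12)^2 / 16, "+") <= 1
  b2 <- outer(outer((xs - 45)^2 / 100, (xs - 30)^2 / 100, "+"),
              (zs - 12)^2 / 16, "+") <= 1
  r[b1] <- 1L; r[b2] <- 2L
  v <- label_volume(r, voxel_geometry(d, c(42, 42, 220)))
  expect_equal(nrow(detect_nanotunnels(v)), 0)
})

test_that("dumbbell phantoms are detected with the right tube length", {
  for (sd in c(3, 8)) {
    p <- volume_params(target_mito_fraction = 0.04,
                       subtype_mix = c(SSM = 0, IFM = 1, PNM = 0),
                       nucleus = FALSE, n_nanotunnels = 1L,
                       projection_prob = c(SSM = 0, IFM = 0, PNM = 0),
                       seed = sd)
    ph <- simulate_cardiomyocyte(p, voxel_geometry(c(200, 200, 40),
                                                   c(42, 42, 220)))
    tun <- detect_nanotunnels(ph$volume)
    expect_equal(nrow(tun), 1)
    expect_lt(abs(tun$tube_length_um / ph$truth$nanotunnels$length_um - 1),
              0.10)
    # defaults bracket the observed nanotunnel dimensions
    expect_gte(tun$tube_diameter_um, 0.2)
    expect_lte(tun$tube_diameter_um, 0.4)
  }
})
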