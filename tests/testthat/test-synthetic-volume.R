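test_that("voxel geometry defaults to the SBF-SEM acquisition sampling", {
  g <- voxel_geometry(c(10, 10, 10))
  expect_equal(g$size_nm, c(13.5, 13.5, 50))
  expect_error(voxel_geometry(c(0, 4, 4)), "dims")
  expect_error(voxel_geometry(c(4, 4, 4), c(-1, 1, 1)), "positive")
})

test_that("a zero-mitochondria request yields only context structures", {
  ph <- simulate_cardiomyocyte(
    volume_params(target_mito_fraction = 0, seed = 3),
    test_geom(c(64, 64, 12)))
  expect_equal(sum(ph$volume$raster), 0)
  expect_equal(ph$truth$true_fraction, 0)
  expect_equal(nrow(ph$truth$objects), 0)
  expect_true(any(ph$volume$sarcolemma_mask))
  expect_true(any(ph$volume$nucleus_mask))
})

test_that("the realized fraction matches the target and the voxel oracle", {
  ph <- simulate_cardiomyocyte(
    volume_params(target_mito_fraction = 0.30, seed = 1),
    test_geom(c(128, 128, 24)))
  # independent exact voxel counting of the emitted raster
  oracle <- sum(ph$volume$raster > 0L) / sum(ph$volume$cm_mask)
  expect_equal(ph$truth$true_fraction, oracle)
  expect_gte(ph$truth$true_fraction, 0.29)
  expect_lte(ph$truth$true_fraction, 0.31)
  # every label in the volume has exactly one ground-truth entry, with
  # exact per-object voxel counts
  labs <- volume_labels(ph$volume)
  expect_setequal(labs, ph$truth$objects$label)
  counts <- tabulate(ph$volume$raster[ph$volume$raster > 0L])
  expect_equal(counts[ph$truth$objects$label], ph$truth$objects$n_vox)
})

test_that("generation is deterministic in the seed", {
  p <- volume_params(target_mito_fraction = 0.15, seed = 7)
  g <- test_geom(c(64, 64, 16), c(84, 84, 420))
  a <- simulate_cardiomyocyte(p, g)
  b <- simulate_cardiomyocyte(p, g)
  expect_identical(a$volume$raster, b$volume$raster)
  expect_identical(a$truth$objects, b$truth$objects)
})

test_that("raising the target never lowers the realized fraction", {
  g <- test_geom(c(64, 64, 16), c(84, 84, 420))
  fr <- vapply(c(0.10, 0.18, 0.26), function(t)
    simulate_cardiomyocyte(volume_params(target_mito_fraction = t,
                                         seed = 5), g)$truth$true_fraction,
    numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("SSM abut the sarcolemma and PNM abut the nuclear envelope", {
  ph <- simulate_cardiomyocyte(
    volume_params(target_mito_fraction = 0.22, seed = 2),
    test_geom(c(96, 96, 20), c(63, 63, 420)))
  tr <- ph$truth$objects
  v <- ph$volume
  gap_to <- function(label, mask) {
    idx <- which(v$raster == label)
    dm <- mitomorph:::dist_to_set(mask, c(1, 1, 1))
    min(dm[idx])
  }
  for (lab in tr$label[tr$subtype == "SSM"])
    expect_lte(gap_to(lab, v$sarcolemma_mask), 2 + 1e-9)
  for (lab in tr$label[tr$subtype == "PNM"])
    expect_lte(gap_to(lab, v$nucleus_mask), 2 + 1e-9)
})

test_that("invalid proportions are rejected", {
  expect_error(volume_params(subtype_mix = c(SSM = 0.6, IFM = 0.6,
                                             PNM = 0.1)), "sum to 1")
  expect_error(volume_params(target_mito_fraction = 1.4), "proportions")
  expect_error(volume_params(projection_length_um = c(mean = 0.5,
                                                      sd = -1)), "sds")
})

test_that("an impossible request raises a capacity error", {
  expect_error(
    simulate_cardiomyocyte(
      volume_params(target_mito_fraction = 0.9, seed = 1),
      test_geom(c(48, 48, 10))),
    class = "mitomorph_capacity_error")
})
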