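test_that("the cristae generator realizes the requested geometry", {
  # defaults are the wild-type dimensions
  p <- cristae_params()
  expect_equal(p$W_O_nm[["mean"]], 36)
  expect_equal(p$W_I_nm[["mean"]], 16)
  expect_error(cristae_params(W_O_nm = c(mean = 14, sd = 1),
                              W_I_nm = c(mean = 16, sd = 1)), "W_I")
  # zero cristae: blank mitochondrion, empty truth
  ph0 <- simulate_cristae_image(cristae_params(n_cristae = 0, seed = 2))
  expect_equal(nrow(ph0$truth$cristae), 0)
  expect_equal(sum(ph0$truth$cristae_mask), 0)
  # seeded determinism
  a <- simulate_cristae_image(cristae_params(seed = 12))
  b <- simulate_cristae_image(cristae_params(seed = 12))
  expect_identical(a$image, b$image)
  expect_identical(a$truth$cristae, b$truth$cristae)
})

test_that("the rasterized outer width matches the request on the mask", {
  ph <- simulate_cristae_image(
    cristae_params(W_O_nm = c(mean = 34, sd = 0),
                   W_I_nm = c(mean = 16, sd = 0),
                   noise_sd = 0, blur_sigma_px = 0, n_cristae = 5,
                   seed = 7))
  tr <- ph$truth
  d <- dim(ph$image); ctr <- d / 2
  phi <- tr$orientation
  ts <- seq(-150, 150, by = 0.25)
  lx <- round(ctr[1] + ts * cos(phi)); ly <- round(ctr[2] + ts * sin(phi))
  ok <- lx >= 1 & lx <= d[1] & ly >= 1 & ly <= d[2]
  hits <- tr$cristae_mask[cbind(lx[ok], ly[ok])]
  runs <- rle(hits)
  widths_nm <- runs$lengths[runs$values] * 0.25 * 2
  # each membrane band is (W_O - W_I)/2 = 9 nm wide, +- 1 px
  expect_true(all(abs(widths_nm - 9) <= 2 + 1e-9))
  # outer span of each doublet: left outer edge to right outer edge
  pos <- which(hits)
  gaps <- which(diff(pos) > 1)
  expect_equal(length(runs$lengths[runs$values]) %% 2, 0)
})

test_that("thresholding recovers the membrane mask", {
  clean <- simulate_cristae_image(cristae_params(noise_sd = 0, seed = 5))
  m <- threshold_membranes(clean$image)
  tm <- clean$truth$membrane_mask
  # agreement up to a 1-px boundary band
  band <- as.matrix(EBImage::distmap(EBImage::Image(1 - tm * 1))) <= 1.5
  expect_true(all(band[m]))
  noisy <- simulate_cristae_image(cristae_params(seed = 5))
  mn <- threshold_membranes(noisy$image)
  iou <- sum(mn & tm) / sum(mn | tm)
  expect_gte(iou, 0.80)
  expect_error(threshold_membranes(matrix(0.5, 8, 8)),
               class = "mitomorph_degenerate_error")
})

test_that("line profiles are geometric and flat where the image is flat", {
  img <- matrix(0.8, 64, 64)
  pr <- line_profile(img, c(5, 5), c(60, 30), pixel_size_nm = 2)
  expect_true(all(diff(pr$pos_nm) > 0))
  expect_equal(max(pr$pos_nm), sqrt(55^2 + 25^2) * 2, tolerance = 0.01)
  expect_equal(var(pr$value), 0)
  expect_equal(nrow(detect_doublets(pr)), 0)
  expect_error(line_profile(img, c(0, 5), c(10, 10)),
               class = "mitomorph_bounds_error")
})

test_that("constructed doublet peaks are recovered within a sample step", {
  pos <- seq(0, 400, by = 0.5)
  v <- rep(0.8, length(pos))
  centres <- c(100, 164, 228)
  for (cc in centres) for (side in c(-13, 13))
    v <- v - 0.5 * exp(-0.5 * ((pos - cc - side) / 4)^2)
  pr <- structure(data.frame(pos_nm = pos, value = v),
                  class = c("cristae_profile", "data.frame"),
                  pixel_size_nm = 2)
  db <- detect_doublets(pr)
  expect_equal(nrow(db), 3)
  expect_lt(max(abs((db$peak_left_nm + db$peak_right_nm) / 2 - centres)),
            0.5 + 1e-9)
})

test_that("a line spanning six cristae yields six doublets", {
  ph <- simulate_cristae_image(cristae_params(n_cristae = 6, seed = 17))
  pr <- line_profile(ph$image, ph$truth$profile_line$p0,
                     ph$truth$profile_line$p1, pixel_size_nm = 2)
  expect_equal(nrow(detect_doublets(pr)), 6)
})

test_that("cristae dimensions are recovered at the reference geometry", {
  wos <- c(); wis <- c(); sss <- c()
  for (sd in 1:6) {
    ph <- simulate_cristae_image(
      cristae_params(W_O_nm = c(mean = 34, sd = 2),
                     W_I_nm = c(mean = 16, sd = 1), seed = sd))
    pr <- line_profile(ph$image, ph$truth$profile_line$p0,
                       ph$truth$profile_line$p1, pixel_size_nm = 2)
    dm <- measure_dims(detect_doublets(pr))
    wos <- c(wos, dm$W_O_nm); wis <- c(wis, dm$W_I_nm)
    sss <- c(sss, dm$S_nm)
  }
  expect_lt(abs(mean(wos) - 34), 2)
  expect_lt(abs(mean(wis) - 16), 2)
  expect_lt(abs(mean(sss, na.rm = TRUE) - 28), 3)
  # the lumen is always narrower than the outer width
  expect_true(all(wis < wos))
})

test_that("spacing is measured edge-to-edge between doublets", {
  ph <- simulate_cristae_image(
    cristae_params(S_nm = c(mean = 28, sd = 0),
                   W_O_nm = c(mean = 36, sd = 0),
                   W_I_nm = c(mean = 16, sd = 0),
                   noise_sd = 0.01, n_cristae = 4, seed = 3))
  pr <- line_profile(ph$image, ph$truth$profile_line$p0,
                     ph$truth$profile_line$p1, pixel_size_nm = 2)
  dm <- measure_dims(detect_doublets(pr))
  expect_lt(max(abs(dm$S_nm[!is.na(dm$S_nm)] - 28)), 2)
})

test_that("quality scores follow the ordered-coverage fractions", {
  scores <- integer(0); covers <- numeric(0)
  for (q in c(1L, 3L, 5L)) {
    ph <- simulate_cristae_image(cristae_params(quality_class = q,
                                                seed = 40 + q))
    sc <- score_quality(ph$image, ph$truth$interior_mask,
                        pixel_size_nm = 2)
    scores <- c(scores, sc$score)
    covers <- c(covers, sc$coverage)
  }
  expect_equal(scores, c(1L, 3L, 5L))
  # score is non-decreasing as coverage decreases
  expect_true(all(diff(covers) < 0))
  expect_error(score_quality(matrix(0.5, 10, 10),
                             matrix(TRUE, 10, 10), 2),
               class = "mitomorph_toosmall_error")
})
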