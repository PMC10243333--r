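test_that("kidney depth evaluates the regression exactly", {
  expect_equal(kidney_depth(10, 80, 2), 4.0368)
  expect_equal(kidney_depth(20, 110, 6), 3.7528)
  # monotone increasing in weight at 0.082 cm/kg
  expect_equal(kidney_depth(11, 80, 2) - kidney_depth(10, 80, 2), 0.082)
  expect_error(kidney_depth(-1, 80, 2), "positive")
  expect_error(kidney_depth(1, 300, 1), "implausible")
})

test_that("attenuation coefficient follows narrow-beam exponential decay", {
  expect_equal(attenuation_coefficient(0), 1)
  expect_equal(attenuation_coefficient(4.0368), exp(-0.153 * 4.0368))
  expect_equal(attenuation_coefficient(4.0368), 0.5392, tolerance = 1e-4)
  depths <- c(2, 4, 6)
  expect_true(all(diff(attenuation_coefficient(depths)) < 0))
  expect_error(attenuation_coefficient(-1), "depth")
})

test_that("ROI counts implement Gates-style background scaling", {
  img <- matrix(2, 8, 8)
  kmask <- matrix(FALSE, 8, 8); kmask[2:6, 2:3] <- TRUE  # 10 px
  bmask <- matrix(FALSE, 8, 8); bmask[8, 1:4] <- TRUE
  rois <- roi_set(list(kmask), bmask)
  cts <- roi_counts(img, rois)
  expect_equal(cts$U, 20)
  expect_equal(cts$B, 20)
  img2 <- img; img2[] <- 1; img2[kmask] <- 5
  cts2 <- roi_counts(img2, rois)
  expect_equal(cts2$U, 50)
  expect_equal(cts2$B, 10)
  expect_error(roi_set(list(matrix(FALSE, 8, 8)), bmask), "empty kidney")
})

test_that("renal uptake formula and its scaling laws hold", {
  expect_equal(renal_uptake(100, 100, 1000), 0)
  expect_equal(renal_uptake(1000, 100, 100000, 0.5), 1.8)
  expect_equal(renal_uptake(1000, 100, 100000, 0.25),
               2 * renal_uptake(1000, 100, 100000, 0.5))
  expect_error(renal_uptake(1, 0, 0), "positive")
  expect_error(renal_uptake(1, 0, 1, 2), "in \\(0, 1\\]")
  # negative uptake is preserved and flagged
  img <- matrix(1, 8, 8); kmask <- matrix(FALSE, 8, 8); kmask[2:3, 2:3] <- TRUE
  bmask <- matrix(FALSE, 8, 8); bmask[6:7, 6:7] <- TRUE
  img[bmask] <- 5
  u <- image_uptake(img, roi_set(list(kmask), bmask), D = 100)
  expect_lt(u$uptake_percent, 0)
  expect_true(u$negative)
})

test_that("ground-truth uptake is recovered from the noiseless full-time map", {
  sp <- phantom_spec(seed = 17L)
  ph <- generate_phantom(sp)
  full10 <- ph$truth$intensity_map * sp$n_frames   # noiseless 10-frame image
  rois <- roi_set(ph$truth$kidney_masks, ph$truth$background_mask)
  u <- image_uptake(full10, rois, D = ph$truth$total_dose_counts, k = 1)
  rel_err <- abs(u$uptake_percent / (ph$truth$true_uptake_fraction * 100) - 1)
  expect_lt(max(rel_err), 0.05)
})

test_that("short-time and full-time uptake agree across a synthetic cohort", {
  specs <- sample_cohort(20, seed = 19L)
  full_u <- c(); short_u <- c()
  for (s in specs) {
    ph <- generate_phantom(s)
    rois <- roi_set(ph$truth$kidney_masks, ph$truth$background_mask)
    D <- ph$truth$total_dose_counts
    uf <- image_uptake(sum_frames(ph$series), rois, D = D, k = 1)
    us <- image_uptake(sum_frames(ph$series, 1:2), rois, D = D * 2 / 10, k = 1)
    full_u <- c(full_u, uf$uptake_percent)
    short_u <- c(short_u, us$uptake_percent)
  }
  ag <- agreement_analysis(full_u, short_u)
  expect_gt(ag$r2, 0.99)
  expect_lt(abs(ag$bias), 0.5)
})

test_that("agreement analysis recovers bias and limits", {
  a <- c(1, 2, 3, 4, 5)
  ag0 <- agreement_analysis(a, a)
  expect_equal(ag0$bias, 0)
  expect_equal(ag0$lower, 0)
  expect_equal(ag0$upper, 0)
  expect_equal(ag0$r2, 1)
  ag1 <- agreement_analysis(a, a + 0.5)
  expect_equal(ag1$bias, 0.5)
  expect_equal(c(ag1$lower, ag1$upper), c(0.5, 0.5))
  set.seed(20)
  x <- rnorm(4000, 20, 3)
  y <- x + rnorm(4000, 0, 0.8)
  ag2 <- agreement_analysis(x, y)
  expect_equal(ag2$bias, 0, tolerance = 0.05)
  expect_equal(ag2$upper - ag2$bias, 1.96 * 0.8, tolerance = 0.08)
  p <- bland_altman_plot(x, y)
  expect_s3_class(p, "ggplot")
})
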