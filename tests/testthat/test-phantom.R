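test_that("zero-intensity phantom produces all-zero frames", {
  sp <- tiny_spec(kidney_mean_counts_per_frame = 0,
                  background_mean_counts_per_frame = 0)
  ph <- generate_phantom(sp)
  expect_true(all(ph$series$frames == 0))
})

test_that("identical spec and seed reproduce the series bit for bit", {
  sp <- tiny_spec(seed = 7L)
  expect_identical(generate_phantom(sp)$series$frames,
                   generate_phantom(sp)$series$frames)
  sp2 <- tiny_spec(seed = 8L)
  expect_false(identical(generate_phantom(sp)$series$frames,
                         generate_phantom(sp2)$series$frames))
})

test_that("kidney 10-frame sum matches the calibrated count level", {
  sp <- phantom_spec(seed = 3L)   # kidney mean 21/frame -> 210 over 10 frames
  ph <- generate_phantom(sp)
  s10 <- sum_frames(ph$series)
  for (mask in ph$truth$kidney_masks) {
    n <- sum(mask)
    se <- sqrt(210 / n)   # Poisson standard error of the region mean
    expect_lt(abs(mean(s10[mask]) - 210), 3 * se)
  }
})

test_that("intensity map reflects the constructed geometry", {
  sp1 <- tiny_spec(kidneys = list(list(center = c(15, 10), semi_axes = c(5, 3),
                                       rotation_deg = 0)),
                   kidney_mean_counts_per_frame = 21,
                   background_mean_counts_per_frame = 0,
                   true_uptake_fraction = 0.2)
  m1 <- intensity_map(sp1)
  mask <- fastdmsa:::rasterize_ellipse(sp1$kidneys[[1]], sp1$image_shape)
  expect_true(all(m1[!mask] == 0))
  expect_true(all(m1[mask] > 0))
  # value at the kidney center equals the per-frame mean
  expect_equal(m1[16, 11], 21)
  # doubling the kidney level doubles the kidney-region integral
  sp2 <- sp1; sp2$kidney_mean_counts_per_frame <- 42
  expect_equal(sum(intensity_map(sp2)), 2 * sum(m1))
})

test_that("per-pixel counts behave as Poisson draws around the map", {
  sp <- phantom_spec(seed = 11L)
  ph <- generate_phantom(sp)
  map <- ph$truth$intensity_map
  body <- map > 0
  expect_gt(sum(body), 1000)
  # across frames each pixel is iid Poisson: variance ~ mean of the stack
  mu_hat <- apply(ph$series$frames, c(1, 2), mean)
  v_hat <- apply(ph$series$frames, c(1, 2), stats::var)
  expect_equal(mean(v_hat[body]) / mean(mu_hat[body]), 1, tolerance = 0.1)
  # sum of k frames has expectation k * map (k = 2 and 10)
  for (k in c(2L, 10L)) {
    sk <- sum_frames(ph$series, seq_len(k))
    expect_equal(mean(sk[body]) / mean(k * map[body]), 1, tolerance = 0.05)
  }
})

test_that("ground-truth masks are disjoint and inside the image", {
  ph <- generate_phantom(tiny_spec())
  overlap <- ph$truth$kidney_masks[[1]] & ph$truth$kidney_masks[[2]]
  expect_false(any(overlap))
  for (m in ph$truth$kidney_masks) {
    expect_false(any(m & ph$truth$background_mask))
    expect_false(any(m[1, ]) || any(m[nrow(m), ]) ||
                   any(m[, 1]) || any(m[, ncol(m)]))
  }
})

test_that("spec validation rejects bad geometry and parameters", {
  expect_error(tiny_spec(kidneys = list(
    list(center = c(2, 2), semi_axes = c(5, 3), rotation_deg = 0))),
    "outside the image")
  expect_error(tiny_spec(kidney_mean_counts_per_frame = -1), "non-negative")
  expect_error(tiny_spec(kidney_mean_counts_per_frame = 1,
                         background_mean_counts_per_frame = 2), "contrast")
  expect_error(tiny_spec(true_uptake_fraction = c(0.6, 0.5)), "sum below 1")
  expect_error(tiny_spec(n_frames = 1L), "n_frames")
})

test_that("phantom motion moves the kidneys before Poisson sampling", {
  motion <- c(list(rigid_transform()),
              replicate(9, rigid_transform(0, c(4, 0), 1), simplify = FALSE))
  sp <- tiny_spec(seed = 5L, motion = motion)
  ph <- generate_phantom(sp)
  map <- intensity_map(sp)
  shifted <- resample_image(map, motion[[2]])
  # frame 2 should match the shifted map better than the unshifted one
  f2 <- ph$series$frames[, , 2]
  expect_lt(mean((f2 - shifted)^2), mean((f2 - map)^2))
})

test_that("series round-trips through the CSV + JSON container", {
  ph <- generate_phantom(tiny_spec(n_frames = 3L))
  prefix <- file.path(withr::local_tempdir(), "series")
  write_series(ph$series, prefix)
  back <- read_series(prefix)
  expect_equal(back$frames, ph$series$frames)
  expect_equal(back$pixel_size_mm, ph$series$pixel_size_mm)
})

test_that("cohort sampling varies count levels and uptake across cases", {
  specs <- sample_cohort(8, tiny_spec(), seed = 2L)
  mus <- vapply(specs, function(s) s$kidney_mean_counts_per_frame[1], numeric(1))
  expect_gt(stats::sd(mus), 0)
  expect_identical(sample_cohort(8, tiny_spec(), seed = 2L), specs)
})
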