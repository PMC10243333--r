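test_that("identity resample returns the input exactly", {
  img <- smooth_image(32)
  expect_identical(resample_image(img, rigid_transform()), img)
  expect_error(resample_image(matrix(c(1, NA, 1, 1), 2)), "finite")
})

test_that("integer translation matches a direct index shift", {
  img <- matrix(0, 20, 20)
  img[6:12, 6:12] <- matrix(seq_len(49), 7, 7)
  out <- resample_image(img, rigid_transform(0, c(0, 3), 1))
  expect_equal(out[, 4:20], img[, 1:17])
  expect_true(all(out[, 1:3] == 0))
  out2 <- resample_image(img, rigid_transform(0, c(-2, 0), 1))
  expect_equal(out2[1:18, ], img[3:20, ])
})

test_that("resampling by T then T^-1 recovers the interior of smooth images", {
  img <- smooth_image(48, seed = 3)
  tr <- rigid_transform(7, c(2.3, -1.7), 1.03)
  back <- resample_image(resample_image(img, tr), invert_transform(tr))
  interior <- 9:40
  expect_lt(max(abs(back[interior, interior] - img[interior, interior])), 0.05)
})

test_that("registering an image to itself yields the identity transform", {
  ph <- generate_phantom(tiny_spec(seed = 2L))
  img <- ph$series$frames[, , 1]
  res <- register_frame(img, img, iterations = 50L)
  expect_lt(abs(res$transform$rotation_deg), 0.5)
  expect_lt(max(abs(res$transform$translation_px)), 0.25)
  expect_lt(abs(res$transform$scale - 1), 0.01)
  expect_lt(res$final_mse, 1e-3)
})

test_that("known translations and rotations are recovered", {
  sp <- phantom_spec(seed = 4L)
  map <- intensity_map(sp)
  set.seed(21)
  target <- matrix(rpois(length(map), map), nrow(map))
  # pure translation, no noise on the source
  tr <- rigid_transform(0, c(3, -2), 1)
  source <- resample_image(target, tr)
  res <- register_frame(source, target)
  inv <- invert_transform(tr)
  expect_lt(max(abs(res$transform$translation_px - inv$translation_px)), 0.5)
  # rotation with Poisson noise at phantom count levels
  tr2 <- rigid_transform(5, c(0, 0), 1)
  moved <- resample_image(map, tr2)
  source2 <- matrix(rpois(length(moved), moved), nrow(map))
  res2 <- register_frame(source2, target)
  expect_lt(abs(res2$transform$rotation_deg - (-5)), 1)
})

test_that("the optimizer does not end worse than it started", {
  sp <- tiny_spec(seed = 9L)
  map <- intensity_map(sp)
  set.seed(31)
  target <- matrix(rpois(length(map), map), nrow(map))
  moved <- resample_image(map, rigid_transform(3, c(2, 2), 1.02))
  source <- matrix(rpois(length(moved), moved), nrow(map))
  res <- register_frame(source, target)
  srcn <- source / mean(source); tgtn <- target / mean(target)
  mse0 <- mean((srcn - tgtn)^2)
  expect_lte(res$final_mse, mse0)
  expect_equal(res$final_mse, res$mse_trace[length(res$mse_trace)])
  expect_length(res$mse_trace, 100L)
})

test_that("resampling approximately preserves total counts for interior content", {
  img <- intensity_map(tiny_spec()) * 10
  out <- resample_image(img, rigid_transform(4, c(2, -3), 1.01))
  expect_lt(abs(sum(out) - sum(img)) / sum(img), 0.02)
})

test_that("all-zero inputs return the identity with a warning", {
  z <- matrix(0, 16, 16)
  expect_warning(res <- register_frame(z, z), "all-zero")
  expect_equal(res$transform$rotation_deg, 0)
  expect_equal(res$transform$scale, 1)
})

test_that("register_series aligns a moving phantom to its first frame", {
  shifts <- list(c(0, 0), c(3, -2), c(-2, 4), c(4, 1))
  motion <- lapply(shifts, function(s) rigid_transform(0, s, 1))
  sp <- phantom_spec(n_frames = 4L, motion = motion, seed = 6L)
  ph <- generate_phantom(sp)
  expect_error(register_series(dynamic_series(ph$series$frames[, , 1,
                                                               drop = FALSE])),
               "at least 2 frames")
  reg <- register_series(ph$series)
  expect_equal(reg$series$frames[, , 1], ph$series$frames[, , 1])
  for (f in 2:4) {
    recovered <- reg$transforms[[f]]$translation_px
    expect_lt(max(abs(recovered - (-shifts[[f]]))), 0.5)
  }
  # registration restores kidney edge sharpness in the summed image;
  # measured on a band around the kidney boundaries (gradients elsewhere are
  # noise-dominated)
  edge_band <- Reduce(`|`, lapply(sp$kidneys, function(kd) {
    r2 <- fastdmsa:::ellipse_r2(kd, sp$image_shape)
    r2 >= 0.6 & r2 <= 1.4
  }))
  pre <- gradient_magnitude(sum_frames(ph$series), edge_band)
  post <- gradient_magnitude(sum_frames(reg$series), edge_band)
  expect_gt(post, pre)
})
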