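test_that("NMSE identities and hand value", {
  y <- matrix(c(2, 2), 1)
  expect_equal(nmse(y, y), 0)
  expect_equal(nmse(matrix(0, 1, 2), y), 100)
  expect_equal(nmse(matrix(c(1, 1), 1), y), 25)
  expect_error(nmse(y, matrix(0, 1, 2)), "all-zero reference")
})

test_that("PSNR hand value and sentinel behavior", {
  y <- matrix(c(10, 10), 1)
  expect_equal(psnr(matrix(c(8, 10), 1), y), 20 * log10(10 / sqrt(2)))
  expect_equal(psnr(matrix(c(8, 10), 1), y), 16.9897, tolerance = 1e-4)
  expect_identical(psnr(y, y), Inf)
})

test_that("more noise means lower PSNR in expectation", {
  set.seed(8)
  y <- matrix(rpois(400, 50), 20)
  p1 <- mean(replicate(30, psnr(y + matrix(rnorm(400, sd = 1), 20), y)))
  p2 <- mean(replicate(30, psnr(y + matrix(rnorm(400, sd = 3), 20), y)))
  expect_gt(p1, p2)
})

test_that("SSIM identities, constant-image closed form, and luminance limit", {
  set.seed(9)
  y <- matrix(rpois(256, 30), 16)
  expect_equal(ssim(y, y), 1)
  # constant images 2 and 4 with L = 4: luminance term only
  val <- ssim(matrix(2, 4, 4), matrix(4, 4, 4), L = 4)
  c1 <- 0.04^2
  expect_equal(val, (2 * 2 * 4 + c1) / (4 + 16 + c1))
  expect_equal(val, 0.8002, tolerance = 5e-4)
  # value below 1 for an offset, increasing toward 1 as the offset shrinks
  s_big <- ssim(y + 5, y, L = 100)
  s_small <- ssim(y + 1, y, L = 100)
  expect_lt(s_big, 1)
  expect_gt(s_small, s_big)
  # windowed variant also perfect on identical images
  expect_equal(ssim(y, y, windowed = TRUE), 1)
})

test_that("SSIM is symmetric while NMSE and PSNR are reference-directed", {
  set.seed(10)
  y <- matrix(rpois(256, 40), 16)
  x <- matrix(rpois(256, 8), 16)
  expect_equal(ssim(x, y, L = max(y)), ssim(y, x, L = max(y)))
  expect_false(isTRUE(all.equal(nmse(x, y), nmse(y, x))))
  expect_false(isTRUE(all.equal(psnr(x, y), psnr(y, x))))
})

test_that("metrics are invariant to a common translation of both images", {
  ph <- generate_phantom(tiny_spec(seed = 14L))
  pad <- function(img) {
    out <- matrix(0, nrow(img) + 12, ncol(img) + 12)
    out[7:(6 + nrow(img)), 7:(6 + ncol(img))] <- img
    out
  }
  y <- pad(sum_frames(ph$series))
  x <- pad(sum_frames(ph$series, c(1, 2)))
  tr <- rigid_transform(0, c(3, 2), 1)
  xs <- resample_image(x, tr); ys <- resample_image(y, tr)
  expect_equal(nmse(xs, ys), nmse(x, y), tolerance = 1e-10)
  expect_equal(psnr(xs, ys), psnr(x, y), tolerance = 1e-10)
  expect_equal(ssim(xs, ys), ssim(x, y), tolerance = 1e-10)
})

test_that("joint histogram correlation follows the attenuation closed form", {
  x <- smooth_image(32, seed = 4) * 100
  jh <- joint_histogram(x, x)
  expect_equal(jh$r2, 1)
  expect_equal(sum(jh$histogram), length(x))
  # all mass on the diagonal for identical inputs
  expect_equal(sum(diag(jh$histogram)), length(x))
  expect_equal(joint_histogram(x, 5 * x)$r2, 1)
  set.seed(15)
  noise_var <- 400
  y <- matrix(rnorm(length(x), sd = 20), nrow(x))
  jh2 <- joint_histogram(x, x + y)
  expected <- stats::var(as.vector(x)) / (stats::var(as.vector(x)) + noise_var)
  expect_equal(jh2$r2, expected, tolerance = 0.05)
})

test_that("aggregation uses linear-interpolation quartiles and excludes Inf", {
  a <- aggregate_metric(c(1, 2, 3))
  expect_equal(a$mean, 2)
  expect_equal(a$median, 2)
  expect_equal(a$q1, 1.5)
  expect_equal(a$q3, 2.5)
  expect_message(b <- aggregate_metric(c(1, 2, 3, Inf)), "1 infinite")
  expect_equal(b$mean, 2)
  expect_equal(b$n_infinite, 1L)
})

test_that("evaluate_split reports per-method rows and perfect-prediction limits", {
  ph <- generate_phantom(tiny_spec(seed = 16L))
  refs <- list(sum_frames(ph$series))
  shorts <- list(sum_frames(ph$series, c(1, 2)))
  ev <- suppressMessages(
    evaluate_split(list(perfect = refs), shorts, refs))
  expect_setequal(unique(ev$summary$method), c("short-time", "perfect"))
  perfect <- ev$per_image[ev$per_image$method == "perfect", ]
  expect_equal(perfect$value[perfect$metric == "nmse_percent"], 0)
  expect_equal(perfect$value[perfect$metric == "ssim"], 1)
})
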