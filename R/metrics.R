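#' Normalized mean squared error (percent)
#'
#' `100 * sum((y - x)^2) / sum(y^2)` where `y` is the reference full-time
#' image and `x` the short-time or predicted image.
#'
#' @param x image under evaluation.
#' @param y reference image of the same shape.
#' @return NMSE in percent.
#' @export
nmse <- function(x, y) {
  stopifnot(all(dim(x) == dim(y)))
  denom <- sum(y^2)
  if (denom == 0) stop("NMSE undefined: all-zero reference image")
  100 * sum((y - x)^2) / denom
}

#' Peak signal-to-noise ratio (dB)
#'
#' `20 * log10(max(y) / sqrt(MSE(x, y)))`; returns `Inf` when the images are
#' identical (zero MSE).
#'
#' @inheritParams nmse
#' @return PSNR in dB (`Inf` if `x == y`).
#' @export
psnr <- function(x, y) {
  stopifnot(all(dim(x) == dim(y)))
  peak <- max(y)
  if (peak <= 0) stop("PSNR undefined: reference maximum is not positive")
  mse <- mean((y - x)^2)
  if (mse == 0) return(Inf)
  20 * log10(peak / sqrt(mse))
}

#' Structural similarity index
#'
#' By default the single-window (global-statistics) form
#' `(2*mu_x*mu_y + c1) * (2*cov_xy + c2) / ((mu_x^2 + mu_y^2 + c1) *
#' (var_x + var_y + c2))` with `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2` and `L`
#' the dynamic range (population variances). `windowed = TRUE` computes the
#' conventional locally windowed SSIM (11x11 Gaussian, sd 1.5) averaged over
#' the image.
#'
#' @inheritParams nmse
#' @param L dynamic range of intensity; defaults to `max(y)`.
#' @param windowed use the locally windowed variant.
#' @return SSIM value (1 for identical images).
#' @export
ssim <- function(x, y, L = NULL, windowed = FALSE) {
  stopifnot(all(dim(x) == dim(y)))
  if (is.null(L)) L <- max(y)
  if (L <= 0) stop("dynamic range L must be positive")
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  if (!windowed) {
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    return(((2 * mx * my + c1) * (2 * cxy + c2)) /
             ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  g <- gaussian_window(11L, 1.5)
  sm <- function(img) filter2d(img, g)
  wn <- sm(matrix(1, nrow(x), ncol(x)))   # border renormalization
  mx <- sm(x) / wn; my <- sm(y) / wn
  vx <- sm(x * x) / wn - mx^2
  vy <- sm(y * y) / wn - my^2
  cxy <- sm(x * y) / wn - mx * my
  mean(((2 * mx * my + c1) * (2 * cxy + c2)) /
         ((mx^2 + my^2 + c1) * (vx + vy + c2)))
}

gaussian_window <- function(size, sigma) {
  half <- (size - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# 2-D correlation with zero padding, via the compiled convolution kernel.
filter2d <- function(image, kernel) {
  k <- nrow(kernel)
  x <- array(image, dim = c(nrow(image), ncol(image), 1L, 1L))
  w <- array(kernel, dim = c(k, k, 1L, 1L))
  out <- cpp_conv_fwd(x, dim(x), w, 0, k, 1L, (k - 1L) %/% 2L)
  matrix(out, nrow(image), ncol(image))
}

#' All three quality metrics of one image against a reference
#'
#' @inheritParams ssim
#' @return `list(nmse_percent, psnr_db, ssim)`.
#' @export
quality_metrics <- function(x, y, L = NULL, windowed = FALSE) {
  list(nmse_percent = nmse(x, y),
       psnr_db = psnr(x, y),
       ssim = ssim(x, y, L = L, windowed = windowed))
}

#' Joint voxel-wise histogram with Pearson correlation
#'
#' Pools voxel pairs over one or more image pairs, bins them on a common
#' 2-D grid, and reports the Pearson correlation of the pooled voxels.
#'
#' @param x,y single images or lists of same-shape paired images.
#' @param bins number of histogram bins per axis.
#' @return `list(histogram, x_breaks, y_breaks, r, r2)`.
#' @export
joint_histogram <- function(x, y, bins = 64L) {
  if (!is.list(x)) x <- list(x)
  if (!is.list(y)) y <- list(y)
  stopifnot(length(x) == length(y))
  xv <- unlist(lapply(x, as.vector), use.names = FALSE)
  yv <- unlist(lapply(y, as.vector), use.names = FALSE)
  stopifnot(length(xv) == length(yv))
  rng <- range(c(xv, yv))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  bx <- seq(rng[1], rng[2], length.out = bins + 1L)
  ix <- pmin(pmax(findInterval(xv, bx, rightmost.closed = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(yv, bx, rightmost.closed = TRUE), 1L), bins)
  h <- matrix(0L, bins, bins)
  tab <- table(factor(ix, levels = seq_len(bins)),
               factor(iy, levels = seq_len(bins)))
  h[] <- as.integer(tab)
  r <- stats::cor(xv, yv)
  list(histogram = h, x_breaks = bx, y_breaks = bx, r = r, r2 = r^2)
}

#' Summary-statistics row: mean (SD) and median (Q1, Q3)
#'
#' Quartiles use linear interpolation (`stats::quantile` type 7). Infinite
#' values (identical-image PSNR) are excluded with a message reporting the
#' count.
#'
#' @param values numeric vector.
#' @return `list(mean, sd, median, q1, q3, n, n_infinite)`.
#' @export
aggregate_metric <- function(values) {
  inf <- !is.finite(values)
  if (any(inf)) message(sum(inf), " infinite value(s) excluded from aggregation")
  v <- values[!inf]
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(mean = mean(v), sd = stats::sd(v), median = q[2], q1 = q[1], q3 = q[3],
       n = length(v), n_infinite = sum(inf))
}

#' Evaluate short-time inputs and model predictions against references
#'
#' Computes per-image NMSE/PSNR/SSIM for the short-time images and for each
#' method's predictions, and aggregates them as mean (SD) and
#' median (Q1, Q3).
#'
#' @param predictions named list of methods, each a list of predicted images
#'   aligned with `references` (may be empty).
#' @param short_times list of short-time images aligned with `references`.
#' @param references list of full-time reference images.
#' @param windowed use windowed SSIM.
#' @return `list(per_image, summary)`: a long per-image `data.frame`
#'   (`image`, `method`, `metric`, `value`) and a summary `data.frame`
#'   (`method`, `metric`, `mean`, `sd`, `median`, `q1`, `q3`).
#' @export
evaluate_split <- function(predictions, short_times, references,
                           windowed = FALSE) {
  methods <- c(list(`short-time` = short_times), predictions)
  rows <- list()
  for (mname in names(methods)) {
    imgs <- methods[[mname]]
    stopifnot(length(imgs) == length(references))
    for (i in seq_along(imgs)) {
      qm <- quality_metrics(imgs[[i]], references[[i]], windowed = windowed)
      rows[[length(rows) + 1L]] <- data.frame(
        image = i, method = mname,
        metric = c("nmse_percent", "psnr_db", "ssim"),
        value = c(qm$nmse_percent, qm$psnr_db, qm$ssim))
    }
  }
  per_image <- do.call(rbind, rows)
  summ <- list()
  for (mname in unique(per_image$method)) {
    for (met in c("nmse_percent", "psnr_db", "ssim")) {
      v <- per_image$value[per_image$method == mname & per_image$metric == met]
      a <- aggregate_metric(v)
      summ[[length(summ) + 1L]] <- data.frame(
        method = mname, metric = met, mean = a$mean, sd = a$sd,
        median = a$median, q1 = a$q1, q3 = a$q3)
    }
  }
  list(per_image = per_image, summary = do.call(rbind, summ))
}
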