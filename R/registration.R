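#' Rigid transform (rotation + translation + isotropic scale)
#'
#' The transform maps source-image coordinates to target-image coordinates:
#' `p_target = scale * R(rotation) %*% (p_source - center) + center + translation`,
#' with rotation about the geometric image center and 0-based `(row, col)`
#' pixel coordinates.
#'
#' @param rotation_deg rotation in degrees about the image center.
#' @param translation_px numeric `(drow, dcol)` translation in pixels.
#' @param scale isotropic scale factor (> 0).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation_deg = 0, translation_px = c(0, 0), scale = 1) {
  if (scale <= 0) stop("scale must be positive")
  structure(list(rotation_deg = rotation_deg,
                 translation_px = as.numeric(translation_px),
                 scale = scale),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: rot %.3f deg, t (%.3f, %.3f) px, scale %.4f\n",
              x$rotation_deg, x$translation_px[1], x$translation_px[2], x$scale))
  invisible(x)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return the inverse transform (same class).
#' @export
invert_transform <- function(transform) {
  th <- -transform$rotation_deg * pi / 180
  s <- 1 / transform$scale
  t <- transform$translation_px
  # inverse: p_src = R(-th)/scale %*% (p_tgt - c - t) + c
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rigid_transform(-transform$rotation_deg,
                  as.numeric(-s * (R %*% t)),
                  s)
}

# Affine matrix A (2 x 3) such that sampling the source at
# p = A[, 1:2] %*% q + A[, 3] renders the transformed image on the target
# grid q (the inverse map of the source->target transform).
transform_inverse_affine <- function(transform, shape) {
  cen <- (shape - 1) / 2
  th <- transform$rotation_deg * pi / 180
  Rinv <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2) / transform$scale
  off <- cen - Rinv %*% (cen + transform$translation_px)
  cbind(Rinv, off)
}

is_identity_transform <- function(transform, tol = 0) {
  abs(transform$rotation_deg) <= tol &&
    all(abs(transform$translation_px) <= tol) &&
    abs(transform$scale - 1) <= tol
}

#' Resample an image under a rigid transform
#'
#' Renders `image` as it appears after applying `transform` (source to
#' target), using bilinear interpolation; samples mapped from outside the
#' source domain are filled with 0. The identity transform returns the input
#' exactly.
#'
#' @param image 2-D numeric matrix with finite values.
#' @param transform a [rigid_transform()].
#' @return matrix of the same shape.
#' @export
resample_image <- function(image, transform) {
  stopifnot(is.matrix(image))
  if (!all(is.finite(image))) stop("image must be finite-valued")
  if (is_identity_transform(transform)) return(image)
  A <- transform_inverse_affine(transform, dim(image))
  cpp_resample_affine(image, A)
}

#' Register one frame to a target frame by iterative MSE minimization
#'
#' Optimizes a rigid transform (rotation, translation, log-scale) so that
#' the resampled source matches the target in mean squared error. Both
#' images are normalized by their means before the MSE is evaluated (so the
#' step size is independent of the count scale); the registered image is
#' produced from the unnormalized source. Optimization is adaptive-moment
#' (Adam) gradient descent on normalized coordinates (translations divided
#' by the image size, rotation in radians), with the gradient obtained by
#' central finite differences and a cosine step-size decay so the iterate
#' settles to sub-pixel precision within the iteration budget.
#'
#' @param source,target same-shape 2-D count images.
#' @param iterations number of optimizer iterations (default 100).
#' @param lr initial step size on normalized coordinates.
#' @param init optional initial [rigid_transform()].
#' @return a `registration_result`: `transform`, `registered_image`,
#'   `final_mse` (on mean-normalized images), and `mse_trace`.
#' @export
register_frame <- function(source, target, iterations = 100L, lr = 0.01,
                           init = NULL) {
  stopifnot(is.matrix(source), is.matrix(target))
  if (!all(dim(source) == dim(target))) stop("source/target shape mismatch")
  if (iterations < 1L) stop("iterations must be >= 1")
  if (all(source == 0) || all(target == 0)) {
    warning("all-zero source or target: returning identity transform")
    tr <- rigid_transform()
    mse <- mean((source - target)^2)
    return(structure(list(transform = tr, registered_image = source,
                          final_mse = mse, mse_trace = rep(mse, iterations)),
                     class = "registration_result"))
  }
  srcn <- source / mean(source)
  tgtn <- target / mean(target)
  n <- max(dim(source))
  par_to_transform <- function(p) {
    rigid_transform(p[1] * 180 / pi, c(p[2], p[3]) * n, exp(p[4]))
  }
  loss <- function(p) {
    mean((resample_image(srcn, par_to_transform(p)) - tgtn)^2)
  }
  p <- c(0, 0, 0, 0)
  if (!is.null(init)) {
    p <- c(init$rotation_deg * pi / 180, init$translation_px / n, log(init$scale))
  }
  m <- v <- numeric(4)
  h <- 1e-3
  trace <- numeric(iterations)
  best <- list(p = p, mse = loss(p))
  for (it in seq_len(iterations)) {
    g <- numeric(4)
    for (j in 1:4) {
      pp <- p; pp[j] <- pp[j] + h
      pm <- p; pm[j] <- pm[j] - h
      g[j] <- (loss(pp) - loss(pm)) / (2 * h)
    }
    lr_t <- lr * 0.5 * (1 + cos(pi * (it - 1) / iterations))
    m <- 0.9 * m + 0.1 * g
    v <- 0.999 * v + 0.001 * g^2
    mh <- m / (1 - 0.9^it)
    vh <- v / (1 - 0.999^it)
    p <- p - lr_t * mh / (sqrt(vh) + 1e-8)
    trace[it] <- loss(p)
    if (trace[it] < best$mse) best <- list(p = p, mse = trace[it])
  }
  # settle on the best iterate so the reported MSE is the minimized one
  p <- best$p
  trace[iterations] <- best$mse
  tr <- par_to_transform(p)
  structure(list(transform = tr,
                 registered_image = resample_image(source, tr),
                 final_mse = best$mse,
                 mse_trace = trace),
            class = "registration_result")
}

#' Register every frame of a dynamic series to its first frame
#'
#' @param series a [dynamic_series()] with at least two frames.
#' @param iterations optimizer iterations per frame.
#' @param lr initial step size.
#' @return `list(series, transforms)`: the motion-corrected series (frame 1
#'   unchanged) and the per-frame transforms (identity for frame 1).
#' @export
register_series <- function(series, iterations = 100L, lr = 0.01) {
  d <- dim(series$frames)
  if (d[3] < 2L) stop("register_series requires at least 2 frames")
  target <- series$frames[, , 1]
  out <- series
  transforms <- vector("list", d[3])
  transforms[[1]] <- rigid_transform()
  for (f in 2:d[3]) {
    res <- register_frame(series$frames[, , f], target, iterations = iterations,
                          lr = lr)
    out$frames[, , f] <- res$registered_image
    transforms[[f]] <- res$transform
  }
  list(series = out, transforms = transforms)
}

#' Mean gradient magnitude of an image (central differences)
#'
#' Used to quantify edge sharpness of summed images before and after
#' registration (motion blurs tissue boundaries; registration restores
#' them). An optional mask restricts the average to a region of interest,
#' e.g. the kidney boundary band.
#'
#' @param image 2-D matrix.
#' @param mask optional logical matrix (same shape); only interior pixels
#'   where the mask is `TRUE` contribute.
#' @return mean gradient magnitude over the selected interior pixels.
#' @export
gradient_magnitude <- function(image, mask = NULL) {
  h <- dim(image)[1]; w <- dim(image)[2]
  gr <- (image[3:h, 2:(w - 1)] - image[1:(h - 2), 2:(w - 1)]) / 2
  gc <- (image[2:(h - 1), 3:w] - image[2:(h - 1), 1:(w - 2)]) / 2
  g <- sqrt(gr^2 + gc^2)
  if (is.null(mask)) return(mean(g))
  mean(g[mask[2:(h - 1), 2:(w - 1)]])
}
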