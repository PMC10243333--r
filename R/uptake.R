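#' Kidney depth from patient attributes (Tauxe regression)
#'
#' `Y = (0.82 W - 0.36 H - 0.06 A + 61.088) / 10` cm, with weight `W` in kg,
#' height `H` in cm and age `A` in years.
#'
#' @param weight_kg,height_cm,age_y patient attributes, all positive.
#' @return kidney depth in cm.
#' @export
kidney_depth <- function(weight_kg, height_cm, age_y) {
  if (any(c(weight_kg, height_cm, age_y) <= 0))
    stop("weight, height and age must all be positive")
  y <- (0.82 * weight_kg - 0.36 * height_cm - 0.06 * age_y + 61.088) / 10
  if (any(y <= 0))
    stop("implausible kidney depth (attribute combination outside the ",
         "regression's domain)")
  y
}

#' Depth-dependent attenuation coefficient
#'
#' Default rule: narrow-beam exponential attenuation `k = exp(-mu * Y)` with
#' `mu = 0.153` per cm (99mTc photons in soft tissue). `k` is the fraction
#' of kidney counts surviving attenuation, in (0, 1].
#'
#' @param depth_cm kidney depth `Y` in cm (>= 0).
#' @param mu linear attenuation coefficient per cm.
#' @param model attenuation rule; only `"exponential"` is defined.
#' @return unitless `k` in (0, 1].
#' @export
attenuation_coefficient <- function(depth_cm, mu = 0.153,
                                    model = "exponential") {
  if (any(depth_cm < 0) || mu <= 0) stop("depth must be >= 0 and mu > 0")
  model <- match.arg(model)
  exp(-mu * depth_cm)
}

#' ROI set for uptake quantification
#'
#' @param kidney_masks list of logical matrices, one per kidney.
#' @param background_mask logical matrix for the background tissue ROI.
#' @param pixel_size_mm pixel edge length in mm.
#' @return an object of class `roi_set`.
#' @export
roi_set <- function(kidney_masks, background_mask, pixel_size_mm = 1.35) {
  for (m in kidney_masks) {
    if (!any(m)) stop("empty kidney mask")
    if (any(m & background_mask)) stop("kidney and background masks overlap")
  }
  if (!any(background_mask)) stop("empty background mask")
  structure(list(kidney_masks = kidney_masks,
                 background_mask = background_mask,
                 pixel_size_mm = pixel_size_mm),
            class = "roi_set")
}

#' Kidney and scaled background counts in an image
#'
#' `U` is the total count inside a kidney ROI; `B` is the mean background
#' count per pixel scaled to the kidney ROI area (Gates-style background
#' correction).
#'
#' @param image count image.
#' @param rois a [roi_set()] matching the image shape.
#' @return `data.frame(kidney, U, B)` with one row per kidney.
#' @export
roi_counts <- function(image, rois) {
  stopifnot(inherits(rois, "roi_set"))
  for (m in c(rois$kidney_masks, list(rois$background_mask))) {
    if (!all(dim(m) == dim(image))) stop("ROI mask shape does not match image")
  }
  bg_per_px <- mean(image[rois$background_mask])
  res <- lapply(seq_along(rois$kidney_masks), function(i) {
    mask <- rois$kidney_masks[[i]]
    data.frame(kidney = i, U = sum(image[mask]), B = bg_per_px * sum(mask))
  })
  do.call(rbind, res)
}

#' Renal uptake percentage
#'
#' `uptake = (U - B) / D * (1 / k) * 100`, the background-corrected kidney
#' count as a fraction of the total dose count, corrected for depth
#' attenuation. Negative values (background exceeding kidney counts) are
#' preserved, not clipped.
#'
#' @param U kidney ROI counts.
#' @param B background counts scaled to the kidney ROI area.
#' @param D total dose counts (> 0).
#' @param k attenuation coefficient in (0, 1].
#' @return uptake in percent.
#' @export
renal_uptake <- function(U, B, D, k = 1) {
  if (any(D <= 0)) stop("total dose count D must be positive")
  if (any(k <= 0 | k > 1)) stop("attenuation coefficient k must be in (0, 1]")
  (U - B) / D * (1 / k) * 100
}

#' Uptake of every kidney in an image
#'
#' Convenience wrapper combining [roi_counts()] and [renal_uptake()].
#'
#' @inheritParams roi_counts
#' @param D total dose count for the image's acquisition time.
#' @param k attenuation coefficient (scalar or per kidney).
#' @return `data.frame(kidney, U, B, k, uptake_percent, negative)`.
#' @export
image_uptake <- function(image, rois, D, k = 1) {
  cts <- roi_counts(image, rois)
  cts$k <- rep_len(k, nrow(cts))
  cts$uptake_percent <- renal_uptake(cts$U, cts$B, D, cts$k)
  cts$negative <- cts$uptake_percent < 0
  cts
}

#' Bland-Altman agreement analysis of paired uptake measurements
#'
#' Reports the Pearson r-squared of `b` against `a`, the bias
#' `mean(b - a)`, and the 95% limits of agreement `bias +/- 1.96 sd(b - a)`.
#'
#' @param a reference measurements (e.g. full-time uptake).
#' @param b comparison measurements, same length (>= 3).
#' @return `list(r2, bias, lower, upper, sd_diff, n)`.
#' @export
agreement_analysis <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  d <- b - a
  sdd <- stats::sd(d)
  r <- stats::cor(a, b)
  list(r2 = r^2, bias = mean(d),
       lower = mean(d) - 1.96 * sdd, upper = mean(d) + 1.96 * sdd,
       sd_diff = sdd, n = length(a))
}

#' Bland-Altman plot
#'
#' Differences against means, with a solid bias line and dashed 95% limits
#' of agreement.
#'
#' @inheritParams agreement_analysis
#' @param title plot title.
#' @return a ggplot object.
#' @export
bland_altman_plot <- function(a, b, title = "Bland-Altman") {
  ag <- agreement_analysis(a, b)
  df <- data.frame(mean = (a + b) / 2, diff = b - a)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ag$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(ag$lower, ag$upper), linetype = "dashed") +
    ggplot2::labs(title = title, x = "Mean of measurements",
                  y = "Difference (b - a)") +
    ggplot2::theme_minimal()
}

#' Scatter plot of paired uptake measurements with Pearson correlation
#'
#' @inheritParams agreement_analysis
#' @param title plot title.
#' @return a ggplot object.
#' @export
uptake_scatter_plot <- function(a, b, title = "Uptake agreement") {
  r2 <- stats::cor(a, b)^2
  df <- data.frame(a = a, b = b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(title = sprintf("%s (R² = %.4f)", title, r2),
                  x = "Reference uptake (%)", y = "Comparison uptake (%)") +
    ggplot2::theme_minimal()
}
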