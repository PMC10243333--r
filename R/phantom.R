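#' Synthetic dynamic planar phantom specification
#'
#' Describes a seeded dynamic planar count-image series emulating a posterior
#' pediatric renal acquisition: two elliptical kidneys with elevated tracer
#' uptake over a low-count elliptical body background, imaged as `n_frames`
#' consecutive frames of independent Poisson counts.
#'
#' The intensity model is additive: inside the body every pixel has expected
#' `background_mean_counts_per_frame` counts; inside a kidney the expected
#' total is `kidney_mean_counts_per_frame` (background plus kidney activity),
#' so the kidney's own contribution per pixel is the excess over background.
#' Ground-truth uptake fractions are the expected kidney-activity counts over
#' the full acquisition divided by the total dose count `D`; when
#' `total_dose_counts` is `NULL`, `D` is derived so that the realized
#' fractions match the requested `true_uptake_fraction` in total.
#'
#' @param image_shape integer vector `(rows, cols)`.
#' @param pixel_size_mm length of a pixel edge in mm.
#' @param n_frames number of frames (>= 2).
#' @param frame_duration_s duration of one frame in seconds.
#' @param kidneys list of two ellipse descriptors, each
#'   `list(center = c(row, col), semi_axes = c(a_row, a_col), rotation_deg)`.
#' @param body ellipse descriptor for the body outline.
#' @param kidney_mean_counts_per_frame expected total counts/pixel/frame
#'   inside each kidney (recycled to the number of kidneys).
#' @param background_mean_counts_per_frame expected counts/pixel/frame in the
#'   body background.
#' @param kidney_profile_amp amplitude of a smooth radial uptake profile
#'   inside each kidney (0 = uniform; larger values concentrate counts toward
#'   the kidney center while preserving the region mean).
#' @param true_uptake_fraction requested fraction of the injected dose in
#'   each kidney; each in (0, 1), summing below 1.
#' @param total_dose_counts simulated whole-dose reference count `D`, or
#'   `NULL` to derive it from the kidney count levels and uptake fractions.
#' @param motion optional list of `n_frames` [rigid_transform()]s applied to
#'   the noiseless intensity map before Poisson sampling (identity allowed).
#' @param seed integer seed; identical spec + seed reproduces the series.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(64L, 64L),
                         pixel_size_mm = 5.4,
                         n_frames = 10L,
                         frame_duration_s = 60,
                         kidneys = list(
                           list(center = c(30, 21), semi_axes = c(10, 6), rotation_deg = -15),
                           list(center = c(30, 43), semi_axes = c(10, 6), rotation_deg = 15)
                         ),
                         body = list(center = c(32, 32), semi_axes = c(28, 22), rotation_deg = 0),
                         kidney_mean_counts_per_frame = 21,
                         background_mean_counts_per_frame = 2,
                         kidney_profile_amp = 0,
                         true_uptake_fraction = c(0.22, 0.20),
                         total_dose_counts = NULL,
                         motion = NULL,
                         seed = 1L) {
  spec <- structure(list(
    image_shape = as.integer(image_shape),
    pixel_size_mm = pixel_size_mm,
    n_frames = as.integer(n_frames),
    frame_duration_s = frame_duration_s,
    kidneys = kidneys,
    body = body,
    kidney_mean_counts_per_frame =
      rep_len(kidney_mean_counts_per_frame, length(kidneys)),
    background_mean_counts_per_frame = background_mean_counts_per_frame,
    kidney_profile_amp = kidney_profile_amp,
    true_uptake_fraction = rep_len(true_uptake_fraction, length(kidneys)),
    total_dose_counts = total_dose_counts,
    motion = motion,
    seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$image_shape) == 2L, all(spec$image_shape >= 8L))
  if (spec$n_frames < 2L) stop("n_frames must be >= 2")
  if (spec$background_mean_counts_per_frame < 0 ||
      any(spec$kidney_mean_counts_per_frame < 0))
    stop("mean counts must be non-negative")
  nonzero <- any(spec$kidney_mean_counts_per_frame > 0) ||
    spec$background_mean_counts_per_frame > 0
  if (nonzero &&
      any(spec$kidney_mean_counts_per_frame <= spec$background_mean_counts_per_frame))
    stop("kidney mean counts must exceed the background mean (no contrast)")
  u <- spec$true_uptake_fraction
  if (any(u <= 0) || any(u >= 1) || sum(u) >= 1)
    stop("true_uptake_fraction must be in (0, 1) per kidney and sum below 1")
  if (!is.null(spec$motion) && length(spec$motion) != spec$n_frames)
    stop("motion must supply one transform per frame")
  for (kd in spec$kidneys) {
    if (!ellipse_inside_image(kd, spec$image_shape))
      stop("kidney ellipse extends outside the image")
  }
  invisible(spec)
}

# Axis-aligned bounding box of a rotated ellipse against the image extent.
ellipse_inside_image <- function(ell, shape) {
  th <- ell$rotation_deg * pi / 180
  a <- ell$semi_axes[1]; b <- ell$semi_axes[2]
  half_r <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
  half_c <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  ell$center[1] - half_r >= 0 && ell$center[1] + half_r <= shape[1] - 1 &&
    ell$center[2] - half_c >= 0 && ell$center[2] + half_c <= shape[2] - 1
}

# Rasterize an ellipse: a pixel belongs to the region if its center
# (integer 0-based row/col coordinates) lies inside the ellipse.
#' @keywords internal
rasterize_ellipse <- function(ell, shape) {
  r <- matrix(0:(shape[1] - 1L), shape[1], shape[2])
  cc <- matrix(0:(shape[2] - 1L), shape[1], shape[2], byrow = TRUE)
  th <- ell$rotation_deg * pi / 180
  dr <- r - ell$center[1]; dc <- cc - ell$center[2]
  u <- (cos(th) * dr + sin(th) * dc) / ell$semi_axes[1]
  v <- (-sin(th) * dr + cos(th) * dc) / ell$semi_axes[2]
  u * u + v * v <= 1
}

# Normalized elliptical radius squared (0 at center, 1 on the boundary).
ellipse_r2 <- function(ell, shape) {
  r <- matrix(0:(shape[1] - 1L), shape[1], shape[2])
  cc <- matrix(0:(shape[2] - 1L), shape[1], shape[2], byrow = TRUE)
  th <- ell$rotation_deg * pi / 180
  dr <- r - ell$center[1]; dc <- cc - ell$center[2]
  u <- (cos(th) * dr + sin(th) * dc) / ell$semi_axes[1]
  v <- (-sin(th) * dr + cos(th) * dc) / ell$semi_axes[2]
  u * u + v * v
}

#' Noiseless per-frame intensity map of a phantom
#'
#' @param spec a [phantom_spec()].
#' @return a numeric matrix of expected counts/pixel/frame.
#' @export
intensity_map <- function(spec) {
  validate_phantom_spec(spec)
  shape <- spec$image_shape
  bg <- spec$background_mean_counts_per_frame
  map <- ifelse(rasterize_ellipse(spec$body, shape), bg, 0)
  for (i in seq_along(spec$kidneys)) {
    mask <- rasterize_ellipse(spec$kidneys[[i]], shape)
    if (!any(mask)) stop("kidney ellipse rasterizes to an empty region")
    excess <- spec$kidney_mean_counts_per_frame[i] - bg
    prof <- rep(1, sum(mask))
    if (spec$kidney_profile_amp > 0) {
      r2 <- ellipse_r2(spec$kidneys[[i]], shape)[mask]
      prof <- 1 + spec$kidney_profile_amp * (1 - r2)
      prof <- prof / mean(prof)   # preserve the region-mean count level
    }
    map[mask] <- bg + excess * prof
  }
  map
}

#' Generate a seeded synthetic dynamic planar series
#'
#' Draws `n_frames` frames of independent Poisson counts around the phantom's
#' noiseless intensity map; if per-frame motion is specified, the map is
#' rigidly resampled before sampling (the patient moves, not the noise).
#'
#' @param spec a [phantom_spec()].
#' @return `list(series, truth)` where `series` is a [dynamic_series()] and
#'   `truth` holds kidney/background masks, realized per-kidney uptake
#'   fractions, the total dose count `D`, the applied motion, and the
#'   noiseless map.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  shape <- spec$image_shape
  map <- intensity_map(spec)
  kidney_masks <- lapply(spec$kidneys, rasterize_ellipse, shape = shape)
  body_mask <- rasterize_ellipse(spec$body, shape)
  bg_mask <- body_mask
  for (m in kidney_masks) bg_mask <- bg_mask & !m
  bg <- spec$background_mean_counts_per_frame
  # Expected kidney-activity counts over the whole acquisition (excess over
  # background, i.e. the kidney's own contribution).
  K <- vapply(seq_along(kidney_masks), function(i) {
    sum(map[kidney_masks[[i]]] - bg) * spec$n_frames
  }, numeric(1))
  D <- spec$total_dose_counts
  if (is.null(D)) D <- sum(K) / sum(spec$true_uptake_fraction)
  if (D == 0) D <- 1   # degenerate zero-intensity phantom: keep uptake defined
  if (D <= 0) stop("total_dose_counts must be positive")
  set.seed(spec$seed)
  frames <- array(0, dim = c(shape[1], shape[2], spec$n_frames))
  for (f in seq_len(spec$n_frames)) {
    mf <- map
    if (!is.null(spec$motion)) mf <- resample_image(map, spec$motion[[f]])
    frames[, , f] <- matrix(stats::rpois(length(mf), as.vector(mf)),
                            shape[1], shape[2])
  }
  series <- dynamic_series(frames, pixel_size_mm = spec$pixel_size_mm,
                           frame_duration_s = spec$frame_duration_s)
  truth <- structure(list(
    kidney_masks = kidney_masks,
    background_mask = bg_mask,
    true_uptake_fraction = K / D,
    total_dose_counts = D,
    applied_motion = spec$motion,
    intensity_map = map
  ), class = "phantom_truth")
  list(series = series, truth = truth)
}

#' Dynamic planar series container
#'
#' @param frames numeric array `(rows, cols, n_frames)` of counts.
#' @param pixel_size_mm pixel edge length in mm.
#' @param frame_duration_s frame duration in seconds.
#' @export
dynamic_series <- function(frames, pixel_size_mm = 1.35, frame_duration_s = 60) {
  stopifnot(length(dim(frames)) == 3L)
  structure(list(frames = frames, pixel_size_mm = pixel_size_mm,
                 frame_duration_s = frame_duration_s),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("dynamic_series: %d frames of %dx%d (%.2f mm px, %.0f s/frame)\n",
              d[3], d[1], d[2], x$pixel_size_mm, x$frame_duration_s))
  invisible(x)
}

#' Sum frames of a dynamic series
#'
#' @param series a [dynamic_series()].
#' @param indices frame indices to sum (default all).
#' @return a count matrix.
#' @export
sum_frames <- function(series, indices = NULL) {
  if (is.null(indices)) indices <- seq_len(dim(series$frames)[3])
  apply(series$frames[, , indices, drop = FALSE], c(1, 2), sum)
}

#' Sample a cohort of case-to-case varying phantom specs
#'
#' Emulates a patient population: kidney count levels and uptake fractions
#' vary across cases around the base spec (count levels normal with sd
#' `count_sd`, fractions uniform in `uptake_range`), and each case gets its
#' own seed derived from `seed`.
#'
#' @param n_cases number of cases.
#' @param base_spec template [phantom_spec()].
#' @param seed cohort seed.
#' @param count_sd across-case standard deviation of the kidney mean
#'   counts/pixel/frame.
#' @param uptake_range range of per-kidney uptake fractions.
#' @return a list of `phantom_spec` objects named `case_001`, ...
#' @export
sample_cohort <- function(n_cases, base_spec = phantom_spec(), seed = 1L,
                          count_sd = 3, uptake_range = c(0.15, 0.27)) {
  set.seed(seed)
  nk <- length(base_spec$kidneys)
  specs <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    s <- base_spec
    mu <- pmax(s$background_mean_counts_per_frame + 2,
               stats::rnorm(nk, mean = s$kidney_mean_counts_per_frame, sd = count_sd))
    s$kidney_mean_counts_per_frame <- mu
    s$true_uptake_fraction <- stats::runif(nk, uptake_range[1], uptake_range[2])
    s$seed <- sample.int(.Machine$integer.max, 1L)
    validate_phantom_spec(s)
    specs[[i]] <- s
  }
  names(specs) <- sprintf("case_%03d", seq_len(n_cases))
  specs
}

#' Write / read a dynamic series with a JSON sidecar
#'
#' Frames are stored as a gzip-compressed CSV (one row per pixel-frame in
#' long form would be wasteful; the matrix is stacked frame by frame) and a
#' JSON sidecar carries the acquisition metadata.
#'
#' @param series a [dynamic_series()].
#' @param prefix file path prefix; writes `<prefix>_frames.csv.gz` and
#'   `<prefix>_meta.json`.
#' @return the prefix, invisibly.
#' @export
write_series <- function(series, prefix) {
  d <- dim(series$frames)
  stacked <- do.call(rbind, lapply(seq_len(d[3]),
                                   function(f) series$frames[, , f]))
  con <- gzfile(paste0(prefix, "_frames.csv.gz"), "w")
  utils::write.table(stacked, con, sep = ",", row.names = FALSE, col.names = FALSE)
  close(con)
  jsonlite::write_json(list(rows = d[1], cols = d[2], n_frames = d[3],
                            pixel_size_mm = series$pixel_size_mm,
                            frame_duration_s = series$frame_duration_s),
                       paste0(prefix, "_meta.json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_series
#' @export
read_series <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  stacked <- as.matrix(utils::read.table(
    gzfile(paste0(prefix, "_frames.csv.gz")), sep = ",", header = FALSE))
  # stacked is (rows * n_frames) x cols with frames stacked along rows
  frames <- array(0, dim = c(meta$rows, meta$cols, meta$n_frames))
  for (f in seq_len(meta$n_frames)) {
    frames[, , f] <- stacked[((f - 1) * meta$rows + 1):(f * meta$rows), ]
  }
  dynamic_series(frames, meta$pixel_size_mm, meta$frame_duration_s)
}

#' Export frames as 16-bit PNG images
#'
#' @param series a [dynamic_series()].
#' @param dir output directory.
#' @param max_value count mapped to white; defaults to the series maximum.
#' @return paths written, invisibly.
#' @export
export_png <- function(series, dir, max_value = NULL) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(max_value)) max_value <- max(series$frames)
  if (max_value <= 0) max_value <- 1
  paths <- character(dim(series$frames)[3])
  for (f in seq_along(paths)) {
    paths[f] <- file.path(dir, sprintf("frame_%02d.png", f))
    png::writePNG(pmin(series$frames[, , f] / max_value, 1), paths[f])
  }
  invisible(paths)
}
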