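# Shared fixtures: small phantoms and tiny networks, all generated in code.

tiny_spec <- function(...) {
  args <- list(
    image_shape = c(32L, 32L),
    kidneys = list(
      list(center = c(15, 10), semi_axes = c(5, 3), rotation_deg = -15),
      list(center = c(15, 21), semi_axes = c(5, 3), rotation_deg = 15)),
    body = list(center = c(16, 16), semi_axes = c(14, 11), rotation_deg = 0))
  over <- list(...)
  for (nm in names(over)) args[[nm]] <- over[[nm]]
  if (length(args$kidneys) == 1L && is.null(list(...)$true_uptake_fraction))
    args$true_uptake_fraction <- 0.2
  do.call(phantom_spec, args)
}

tiny_dncnn <- function(units = 2L, n_filters = 3L, seed = 1L)
  build_dncnn(n_filters = n_filters, units = units, seed = seed)

tiny_win5rb <- function(n_filters = 3L, kernel = 5L, seed = 1L)
  build_win5rb(n_filters = n_filters, kernel = kernel, seed = seed)

tiny_resunet <- function(level_filters = c(3L, 4L), bridge_filters = 6L,
                         seed = 1L)
  build_resunet(level_filters = level_filters, bridge_filters = bridge_filters,
                seed = seed)

# Smooth synthetic image (sum of Gaussian blobs) for interpolation tests.
smooth_image <- function(n = 48, seed = 1) {
  set.seed(seed)
  r <- matrix(0:(n - 1), n, n)
  cc <- t(r)
  img <- matrix(0, n, n)
  for (i in 1:3) {
    cy <- runif(1, n * 0.3, n * 0.7); cx <- runif(1, n * 0.3, n * 0.7)
    s <- runif(1, 4, 8)
    img <- img + exp(-((r - cy)^2 + (cc - cx)^2) / (2 * s^2))
  }
  img
}

randomize_final_conv <- function(model, sd = 0.1, seed = 99) {
  set.seed(seed)
  nm <- switch(model$arch, dncnn = "cf_w", win5rb = "c5_w", resunet = "final_w")
  model$params[[nm]][] <- rnorm(length(model$params[[nm]]), sd = sd)
  model
}
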