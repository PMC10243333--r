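#' Enumerate all k-frame index subsets
#'
#' All `choose(n_frames, k)` unordered subsets of frame indices, in
#' deterministic lexicographic order. With 10 frames and k = 2 this yields
#' the 45 short-time inputs per case.
#'
#' @param n_frames number of frames.
#' @param k subset size, `1 <= k <= n_frames`.
#' @return list of integer vectors (1-based frame indices).
#' @export
enumerate_subsets <- function(n_frames, k) {
  if (k < 1 || k > n_frames) stop("k must satisfy 1 <= k <= n_frames")
  m <- utils::combn(seq_len(n_frames), k)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

#' Build short-time / full-time training pairs from a series
#'
#' For every 2-frame subset, the short-time image is the exact integer sum
#' of the two frames and the full-time target is the sum of all frames
#' (identical across a case's pairs).
#'
#' @param series a [dynamic_series()] with at least 2 frames.
#' @param case_id identifier attached to every pair.
#' @return list of `training_pair` objects with fields `case_id`,
#'   `frame_indices`, `short_time`, `full_time`.
#' @export
build_pairs <- function(series, case_id = "case") {
  n <- dim(series$frames)[3]
  if (n < 2L) stop("build_pairs requires at least 2 frames")
  full <- sum_frames(series)
  lapply(enumerate_subsets(n, 2L), function(idx) {
    structure(list(case_id = case_id,
                   frame_indices = idx,
                   short_time = series$frames[, , idx[1]] + series$frames[, , idx[2]],
                   full_time = full),
              class = "training_pair")
  })
}

#' Case-level train / validation / test split
#'
#' Cases (never individual pairs) are partitioned so no case contributes to
#' two splits. Counts are the largest-remainder rounding of
#' `fractions * length(case_ids)`; assignment is a seeded random
#' permutation.
#'
#' @param case_ids character or integer vector of case identifiers.
#' @param fractions length-3 non-negative vector summing to 1
#'   (train, validation, test).
#' @param seed integer seed.
#' @return `list(train, validation, test)` of case ids.
#' @export
split_cases <- function(case_ids, fractions = c(109, 23, 23) / 155, seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n <- length(case_ids)
  raw <- fractions * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(rem)]] <- counts[order_rem[seq_len(rem)]] + 1
  }
  set.seed(seed)
  perm <- sample(case_ids)
  list(train = perm[seq_len(counts[1])],
       validation = perm[counts[1] + seq_len(counts[2])],
       test = perm[counts[1] + counts[2] + seq_len(counts[3])])
}

#' Standardize an image to zero mean and unit standard deviation
#'
#' Uses the population (divide-by-N) standard deviation so that tiny images
#' standardize exactly. The inverse recovers the count scale.
#'
#' @param image numeric matrix with nonzero variance.
#' @return `list(image, params)` with `params = list(mean, sd)`.
#' @export
standardize <- function(image) {
  m <- mean(image)
  s <- sqrt(mean((image - m)^2))
  if (s <= .Machine$double.eps * max(1, abs(m)))
    stop("constant image: standard deviation is zero")
  list(image = (image - m) / s, params = list(mean = m, sd = s))
}

#' @rdname standardize
#' @param params a `list(mean, sd)` as returned by [standardize()].
#' @export
inverse_standardize <- function(image, params) {
  image * params$sd + params$mean
}

#' Standardize a training pair with the input image's statistics
#'
#' Both the short-time input and the full-time target are standardized with
#' the input's mean and standard deviation, so the roughly fivefold count
#' amplification is a learnable, invertible mapping and predictions can be
#' returned to the count scale with the input's parameters.
#'
#' @param pair a `training_pair` from [build_pairs()].
#' @return the pair augmented with `input_std`, `target_std`, `params`.
#' @export
standardize_pair <- function(pair) {
  st <- standardize(pair$short_time)
  pair$input_std <- st$image
  pair$target_std <- (pair$full_time - st$params$mean) / st$params$sd
  pair$params <- st$params
  pair
}
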