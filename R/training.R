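#' Training configuration
#'
#' Defaults follow the training protocol: MSE loss, Adam optimizer, initial
#' learning rate 1e-4, at most 50 epochs, batch size 8, no learning-rate
#' schedule, with the checkpoint taken at the minimum validation loss.
#'
#' @param learning_rate Adam step size.
#' @param max_epochs number of epochs (all are run; selection is post hoc).
#' @param batch_size images per gradient step.
#' @param seed seed controlling shuffling (initialization is seeded at model
#'   construction).
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, max_epochs = 50L,
                         batch_size = 8L, seed = 1L) {
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 loss = "mse", optimizer = "adam"),
            class = "train_config")
}

pairs_to_tensors <- function(pairs) {
  stopifnot(length(pairs) >= 1L)
  if (is.null(pairs[[1]]$input_std))
    pairs <- lapply(pairs, standardize_pair)
  d <- dim(pairs[[1]]$input_std)
  X <- array(0, dim = c(d[1], d[2], 1L, length(pairs)))
  Y <- array(0, dim = c(d[1], d[2], 1L, length(pairs)))
  for (i in seq_along(pairs)) {
    X[, , 1L, i] <- pairs[[i]]$input_std
    Y[, , 1L, i] <- pairs[[i]]$target_std
  }
  list(X = X, Y = Y)
}

eval_loss <- function(model, X, Y, batch_size) {
  n <- dim(X)[4]
  tot <- 0
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    xb <- X[, , , i:j, drop = FALSE]
    yb <- Y[, , , i:j, drop = FALSE]
    out <- model_forward(model, xb, training = FALSE)$out
    tot <- tot + sum((out - yb)^2)
    i <- j + 1L
  }
  tot / length(X)
}

#' Train a model on standardized training pairs
#'
#' Minimizes the MSE between the network output and the standardized
#' full-time target with Adam. Data order is reshuffled every epoch from the
#' config seed; exactly `max_epochs` epochs are run and the returned model
#' carries the weights of the epoch with minimum validation loss (computed
#' in standardized space, the training objective's space).
#'
#' @param model a `dmsa_model`.
#' @param train_pairs,val_pairs non-empty lists of training pairs
#'   (standardized on the fly via [standardize_pair()] if needed).
#' @param config a [train_config()].
#' @param verbose print per-epoch losses.
#' @return `list(model, history)` where `history` is a `data.frame`
#'   (`epoch`, `train_loss`, `val_loss`) with attributes `best_epoch` and
#'   `best_val_loss`.
#' @export
train <- function(model, train_pairs, val_pairs, config = train_config(),
                  verbose = FALSE) {
  if (length(train_pairs) == 0L || length(val_pairs) == 0L)
    stop("train and validation sets must be non-empty")
  tr <- pairs_to_tensors(train_pairs)
  va <- pairs_to_tensors(val_pairs)
  n <- dim(tr$X)[4]
  state <- adam_init(model$params)
  set.seed(config$seed)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(val = Inf, params = model$params, stats = model$stats,
               epoch = 0L)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    i <- 1L
    while (i <= n) {
      j <- min(i + config$batch_size - 1L, n)
      idx <- ord[i:j]
      xb <- tr$X[, , , idx, drop = FALSE]
      yb <- tr$Y[, , , idx, drop = FALSE]
      fw <- model_forward(model, xb, training = TRUE)
      model$stats <- fw$stats
      diff <- fw$out - yb
      loss <- mean(diff * diff)
      if (!is.finite(loss))
        stop(sprintf("non-finite training loss at epoch %d (diverged); ",
                     epoch), "reduce the learning rate")
      grads <- model_backward(model, fw$cache, 2 * diff / length(diff))
      upd <- adam_step(model$params, grads, state, config$learning_rate)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + loss * length(idx)
      i <- j + 1L
    }
    ep_loss <- ep_loss / n
    val_loss <- eval_loss(model, va$X, va$Y, config$batch_size)
    history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss,
                                         val_loss = val_loss))
    if (val_loss < best$val) {
      best <- list(val = val_loss, params = model$params, stats = model$stats,
                   epoch = epoch)
    }
    if (verbose)
      message(sprintf("epoch %d: train %.5f  val %.5f", epoch, ep_loss, val_loss))
  }
  model$params <- best$params
  model$stats <- best$stats
  attr(history, "best_epoch") <- best$epoch
  attr(history, "best_val_loss") <- best$val
  list(model = model, history = history)
}

#' Predict a count-scale full-time image from a short-time image
#'
#' Standardizes the input, runs the network in inference mode (frozen
#' running statistics), inverse-standardizes with the input's parameters,
#' and clips at zero (counts are non-negative).
#'
#' @param model a trained `dmsa_model`.
#' @param short_time count-scale short-time image.
#' @param params optional `list(mean, sd)`; computed from `short_time` if
#'   missing.
#' @return predicted full-time image on the count scale, minimum 0.
#' @export
predict_counts <- function(model, short_time, params = NULL) {
  if (is.null(params)) {
    st <- standardize(short_time)
    z <- st$image
    params <- st$params
  } else {
    z <- (short_time - params$mean) / params$sd
  }
  out <- model_forward(model, z, training = FALSE)$out
  pred <- inverse_standardize(matrix(out, nrow(short_time), ncol(short_time)),
                              params)
  pmax(pred, 0)
}
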