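# Minimal convolutional-network engine: conv / batch-norm / ReLU layers with
# hand-derived backward passes over the compiled im2col GEMM kernels, plus
# the Adam optimizer. Tensors are numeric arrays (H, W, C, N).

as_tensor <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  stopifnot(length(dim(x)) == 4L)
  x
}

conv_init <- function(k, cin, cout, zero = FALSE) {
  n <- k * k * cin * cout
  w <- if (zero) numeric(n) else stats::rnorm(n, sd = sqrt(2 / (k * k * cin)))
  list(w = array(w, dim = c(k, k, cin, cout)), b = numeric(cout))
}

conv_fwd <- function(x, w, b, stride = 1L) {
  k <- dim(w)[1]
  cpp_conv_fwd(x, dim(x), w, b, k, as.integer(stride), (k - 1L) %/% 2L)
}

conv_bwd <- function(x, w, dy, stride = 1L) {
  k <- dim(w)[1]
  cpp_conv_bwd(x, dim(x), w, dy, k, as.integer(stride), (k - 1L) %/% 2L)
}

relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

relu_bwd <- function(y, dy) {
  dy[y <= 0] <- 0
  dy
}

bn_init <- function(C) list(gamma = rep(1, C), beta = rep(0, C))
bn_stats_init <- function(C) list(mean = rep(0, C), var = rep(1, C))

# Channel-major matrix view of an (H, W, C, N) tensor: rows are pixels x
# samples, columns are channels.
to_cmat <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(m) <- c(d[1] * d[2] * d[4], d[3])
  m
}

from_cmat <- function(m, d) {
  dim(m) <- c(d[1], d[2], d[4], d[3])
  aperm(m, c(1L, 2L, 4L, 3L))
}

bn_fwd <- function(x, gamma, beta, stats, training, momentum = 0.1,
                   eps = 1e-5) {
  d <- dim(x)
  xm <- to_cmat(x)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    v <- colMeans(xc * xc)
    stats$mean <- (1 - momentum) * stats$mean + momentum * mu
    stats$var <- (1 - momentum) * stats$var + momentum * v
  } else {
    mu <- stats$mean
    v <- stats$var
    xc <- sweep(xm, 2L, mu)
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, istd, `*`)
  ym <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(y = from_cmat(ym, d), stats = stats,
       cache = list(xhat = xhat, istd = istd, gamma = gamma, d = d,
                    training = training))
}

bn_bwd <- function(cache, dy) {
  d <- cache$d
  dym <- to_cmat(dy)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  if (!cache$training) {
    dxm <- sweep(dym, 2L, cache$gamma * cache$istd, `*`)
    return(list(dx = from_cmat(dxm, d), dgamma = dgamma, dbeta = dbeta))
  }
  n <- nrow(dym)
  dxhat <- sweep(dym, 2L, cache$gamma, `*`)
  t1 <- sweep(dxhat, 2L, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), `*`)
  dxm <- sweep(t1 - t2, 2L, cache$istd, `*`)
  list(dx = from_cmat(dxm, d), dgamma = dgamma, dbeta = dbeta)
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  ro <- seq(1L, d[1], by = 2L); re <- seq(2L, d[1], by = 2L)
  co <- seq(1L, d[2], by = 2L); ce <- seq(2L, d[2], by = 2L)
  dy[ro, co, , , drop = FALSE] + dy[ro, ce, , , drop = FALSE] +
    dy[re, co, , , drop = FALSE] + dy[re, ce, , , drop = FALSE]
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[2] == db[2], da[4] == db[4])
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_ch <- function(x, c1) {
  d <- dim(x)
  list(x[, , seq_len(c1), , drop = FALSE],
       x[, , (c1 + 1L):d[3], , drop = FALSE])
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
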