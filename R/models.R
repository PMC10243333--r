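# The three denoising architectures. Each maps a standardized short-time
# image to a standardized full-time prediction of identical shape, with
# zero-padded convolutions throughout. Forward passes record the caches
# needed by the hand-derived backward passes.

#' Architecture specification
#'
#' @param name one of `"dncnn"`, `"win5rb"`, `"resunet"`.
#' @param n_filters filters for the sequential architectures (default 64).
#' @param dncnn_units number of Conv+BN+ReLU middle units of DnCNN.
#' @param win5rb_kernel kernel size of Win5RB.
#' @param resunet_level_filters encoder filters per level.
#' @param resunet_bridge_filters filters at the bridge.
#' @param seed initialization seed.
#' @return a list usable with [build_model()].
#' @export
architecture_spec <- function(name = c("dncnn", "win5rb", "resunet"),
                              n_filters = 64L, dncnn_units = 15L,
                              win5rb_kernel = 7L,
                              resunet_level_filters = c(64L, 128L, 256L),
                              resunet_bridge_filters = 512L,
                              seed = 1L) {
  list(name = match.arg(name), n_filters = n_filters,
       dncnn_units = dncnn_units, win5rb_kernel = win5rb_kernel,
       resunet_level_filters = resunet_level_filters,
       resunet_bridge_filters = resunet_bridge_filters, seed = seed)
}

#' Build a model from an architecture specification
#'
#' @param spec an [architecture_spec()].
#' @return a `dmsa_model`.
#' @export
build_model <- function(spec) {
  switch(spec$name,
         dncnn = build_dncnn(n_filters = spec$n_filters, units = spec$dncnn_units,
                             seed = spec$seed),
         win5rb = build_win5rb(n_filters = spec$n_filters,
                               kernel = spec$win5rb_kernel, seed = spec$seed),
         resunet = build_resunet(level_filters = spec$resunet_level_filters,
                                 bridge_filters = spec$resunet_bridge_filters,
                                 seed = spec$seed))
}

new_model <- function(arch, cfg, params, stats, n_conv) {
  structure(list(arch = arch, cfg = cfg, params = params, stats = stats,
                 n_conv = n_conv), class = "dmsa_model")
}

#' @export
print.dmsa_model <- function(x, ...) {
  cat(sprintf("dmsa_model '%s': %d convolution layers, %d parameters\n",
              x$arch, x$n_conv, n_params(x)))
  invisible(x)
}

#' Total number of trainable parameters of a model
#' @param model a `dmsa_model`.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Number of convolution layers of a model
#' @param model a `dmsa_model`.
#' @export
count_conv_layers <- function(model) model$n_conv

#' Receptive field side length of a sequential model
#'
#' For a stack of `n` same-padded convolutions of kernel `k`:
#' `n * (k - 1) + 1`.
#'
#' @param model a `dmsa_model` built by [build_dncnn()] or [build_win5rb()].
#' @export
receptive_field <- function(model) {
  if (!model$arch %in% c("dncnn", "win5rb"))
    stop("receptive_field is defined for the sequential architectures only")
  model$n_conv * (model$cfg$kernel - 1L) + 1L
}

# ---- DnCNN -----------------------------------------------------------------

#' DnCNN denoiser
#'
#' Conv3x3+ReLU, then `units` repetitions of Conv3x3+BN+ReLU, then a final
#' Conv3x3 predicting a residual; the output is
#' `input + residual_sign * residual` (canonical form: sign -1, i.e. the
#' predicted noise is subtracted from the input). The final convolution is
#' zero-initialized so the untrained network is the identity mapping.
#'
#' @param n_filters filters per layer.
#' @param units number of middle Conv+BN+ReLU units (17 convolutions total
#'   with the default 15).
#' @param residual_sign -1 (subtract residual) or +1 (add).
#' @param seed initialization seed (Kaiming fan-in).
#' @return a `dmsa_model`.
#' @export
build_dncnn <- function(n_filters = 64L, units = 15L, residual_sign = -1,
                        seed = 1L) {
  stopifnot(residual_sign %in% c(-1, 1))
  set.seed(seed)
  params <- list()
  stats <- list()
  c1 <- conv_init(3L, 1L, n_filters)
  params$c1_w <- c1$w; params$c1_b <- c1$b
  for (i in seq_len(units)) {
    ci <- conv_init(3L, n_filters, n_filters)
    bi <- bn_init(n_filters)
    params[[sprintf("c%d_w", i + 1L)]] <- ci$w
    params[[sprintf("c%d_b", i + 1L)]] <- ci$b
    params[[sprintf("bn%d_g", i + 1L)]] <- bi$gamma
    params[[sprintf("bn%d_b", i + 1L)]] <- bi$beta
    stats[[sprintf("bn%d", i + 1L)]] <- bn_stats_init(n_filters)
  }
  cf <- conv_init(3L, n_filters, 1L, zero = TRUE)
  params$cf_w <- cf$w; params$cf_b <- cf$b
  new_model("dncnn",
            list(n_filters = n_filters, units = units, kernel = 3L,
                 residual_sign = residual_sign),
            params, stats, n_conv = units + 2L)
}

dncnn_fwd <- function(model, x, training) {
  P <- model$params
  U <- model$cfg$units
  cache <- list(x = x)
  a1 <- conv_fwd(x, P$c1_w, P$c1_b)
  h <- relu_fwd(a1)
  cache$h1 <- h
  cache$units <- vector("list", U)
  stats <- model$stats
  for (i in seq_len(U)) {
    nm <- sprintf("bn%d", i + 1L)
    ci <- conv_fwd(h, P[[sprintf("c%d_w", i + 1L)]], P[[sprintf("c%d_b", i + 1L)]])
    bn <- bn_fwd(ci, P[[sprintf("bn%d_g", i + 1L)]], P[[sprintf("bn%d_b", i + 1L)]],
                 stats[[nm]], training)
    stats[[nm]] <- bn$stats
    hn <- relu_fwd(bn$y)
    cache$units[[i]] <- list(h_in = h, bn_cache = bn$cache, h_out = hn)
    h <- hn
  }
  res <- conv_fwd(h, P$cf_w, P$cf_b)
  cache$h_last <- h
  out <- x + model$cfg$residual_sign * res
  list(out = out, cache = cache, stats = stats)
}

dncnn_bwd <- function(model, cache, dout) {
  P <- model$params
  U <- model$cfg$units
  g <- list()
  dres <- model$cfg$residual_sign * dout
  bf <- conv_bwd(cache$h_last, P$cf_w, dres)
  g$cf_w <- bf$dw; g$cf_b <- bf$db
  dh <- bf$dx
  for (i in rev(seq_len(U))) {
    u <- cache$units[[i]]
    dbn <- relu_bwd(u$h_out, dh)
    bb <- bn_bwd(u$bn_cache, dbn)
    g[[sprintf("bn%d_g", i + 1L)]] <- bb$dgamma
    g[[sprintf("bn%d_b", i + 1L)]] <- bb$dbeta
    cb <- conv_bwd(u$h_in, P[[sprintf("c%d_w", i + 1L)]], bb$dx)
    g[[sprintf("c%d_w", i + 1L)]] <- cb$dw
    g[[sprintf("c%d_b", i + 1L)]] <- cb$db
    dh <- cb$dx
  }
  da1 <- relu_bwd(cache$h1, dh)
  cb <- conv_bwd(cache$x, P$c1_w, da1)
  g$c1_w <- cb$dw; g$c1_b <- cb$db
  g   # skip path gradient (identity) handled by the caller via + dout
}

# ---- Win5RB ----------------------------------------------------------------

#' Win5RB denoiser
#'
#' Four Conv+BN+ReLU layers followed by one Conv+BN layer, all with a
#' `kernel x kernel` kernel (7 by default), plus an additive input-to-output
#' skip connection. The final convolution is zero-initialized so the
#' untrained network is the identity mapping.
#'
#' @param n_filters filters per layer.
#' @param kernel kernel size.
#' @param seed initialization seed.
#' @return a `dmsa_model`.
#' @export
build_win5rb <- function(n_filters = 64L, kernel = 7L, seed = 1L) {
  set.seed(seed)
  params <- list(); stats <- list()
  cins <- c(1L, rep(n_filters, 3L))
  for (i in 1:4) {
    ci <- conv_init(kernel, cins[i], n_filters)
    bi <- bn_init(n_filters)
    params[[sprintf("c%d_w", i)]] <- ci$w
    params[[sprintf("c%d_b", i)]] <- ci$b
    params[[sprintf("bn%d_g", i)]] <- bi$gamma
    params[[sprintf("bn%d_b", i)]] <- bi$beta
    stats[[sprintf("bn%d", i)]] <- bn_stats_init(n_filters)
  }
  c5 <- conv_init(kernel, n_filters, 1L, zero = TRUE)
  b5 <- bn_init(1L)
  params$c5_w <- c5$w; params$c5_b <- c5$b
  params$bn5_g <- b5$gamma; params$bn5_b <- b5$beta
  stats$bn5 <- bn_stats_init(1L)
  new_model("win5rb", list(n_filters = n_filters, kernel = kernel),
            params, stats, n_conv = 5L)
}

win5rb_fwd <- function(model, x, training) {
  P <- model$params
  stats <- model$stats
  cache <- list(x = x, layers = vector("list", 5L))
  h <- x
  for (i in 1:5) {
    nm <- sprintf("bn%d", i)
    ci <- conv_fwd(h, P[[sprintf("c%d_w", i)]], P[[sprintf("c%d_b", i)]])
    bn <- bn_fwd(ci, P[[sprintf("bn%d_g", i)]], P[[sprintf("bn%d_b", i)]],
                 stats[[nm]], training)
    stats[[nm]] <- bn$stats
    hn <- if (i < 5L) relu_fwd(bn$y) else bn$y
    cache$layers[[i]] <- list(h_in = h, bn_cache = bn$cache, h_out = hn)
    h <- hn
  }
  list(out = x + h, cache = cache, stats = stats)
}

win5rb_bwd <- function(model, cache, dout) {
  P <- model$params
  g <- list()
  dh <- dout
  for (i in 5:1) {
    ly <- cache$layers[[i]]
    dbn <- if (i < 5L) relu_bwd(ly$h_out, dh) else dh
    bb <- bn_bwd(ly$bn_cache, dbn)
    g[[sprintf("bn%d_g", i)]] <- bb$dgamma
    g[[sprintf("bn%d_b", i)]] <- bb$dbeta
    cb <- conv_bwd(ly$h_in, P[[sprintf("c%d_w", i)]], bb$dx)
    g[[sprintf("c%d_w", i)]] <- cb$dw
    g[[sprintf("c%d_b", i)]] <- cb$db
    dh <- cb$dx
  }
  g
}

# ---- ResUnet ---------------------------------------------------------------

ru_names <- function(name, proj) {
  nms <- c(sprintf("%s_bn1_g", name), sprintf("%s_bn1_b", name),
           sprintf("%s_c1_w", name), sprintf("%s_c1_b", name),
           sprintf("%s_bn2_g", name), sprintf("%s_bn2_b", name),
           sprintf("%s_c2_w", name), sprintf("%s_c2_b", name))
  if (proj) nms <- c(nms, sprintf("%s_proj_w", name), sprintf("%s_proj_b", name))
  nms
}

ru_init <- function(name, cin, cout, stride) {
  params <- list(); stats <- list()
  b1 <- bn_init(cin)
  params[[sprintf("%s_bn1_g", name)]] <- b1$gamma
  params[[sprintf("%s_bn1_b", name)]] <- b1$beta
  stats[[sprintf("%s_bn1", name)]] <- bn_stats_init(cin)
  c1 <- conv_init(3L, cin, cout)
  params[[sprintf("%s_c1_w", name)]] <- c1$w
  params[[sprintf("%s_c1_b", name)]] <- c1$b
  b2 <- bn_init(cout)
  params[[sprintf("%s_bn2_g", name)]] <- b2$gamma
  params[[sprintf("%s_bn2_b", name)]] <- b2$beta
  stats[[sprintf("%s_bn2", name)]] <- bn_stats_init(cout)
  c2 <- conv_init(3L, cout, cout)
  params[[sprintf("%s_c2_w", name)]] <- c2$w
  params[[sprintf("%s_c2_b", name)]] <- c2$b
  if (stride != 1L || cin != cout) {
    pr <- conv_init(1L, cin, cout)
    params[[sprintf("%s_proj_w", name)]] <- pr$w
    params[[sprintf("%s_proj_b", name)]] <- pr$b
  }
  list(params = params, stats = stats)
}

# Pre-activation residual unit: (BN -> ReLU -> Conv) x 2 plus an identity or
# 1x1-projection shortcut (projection when the stride or channel count
# changes).
ru_fwd <- function(P, stats, name, x, stride, training) {
  bn1 <- bn_fwd(x, P[[sprintf("%s_bn1_g", name)]], P[[sprintf("%s_bn1_b", name)]],
                stats[[sprintf("%s_bn1", name)]], training)
  stats[[sprintf("%s_bn1", name)]] <- bn1$stats
  a1 <- relu_fwd(bn1$y)
  c1 <- conv_fwd(a1, P[[sprintf("%s_c1_w", name)]], P[[sprintf("%s_c1_b", name)]],
                 stride)
  bn2 <- bn_fwd(c1, P[[sprintf("%s_bn2_g", name)]], P[[sprintf("%s_bn2_b", name)]],
                stats[[sprintf("%s_bn2", name)]], training)
  stats[[sprintf("%s_bn2", name)]] <- bn2$stats
  a2 <- relu_fwd(bn2$y)
  c2 <- conv_fwd(a2, P[[sprintf("%s_c2_w", name)]], P[[sprintf("%s_c2_b", name)]], 1L)
  proj <- !is.null(P[[sprintf("%s_proj_w", name)]])
  short <- if (proj) {
    conv_fwd(x, P[[sprintf("%s_proj_w", name)]], P[[sprintf("%s_proj_b", name)]],
             stride)
  } else x
  list(y = c2 + short, stats = stats,
       cache = list(x = x, bn1 = bn1$cache, a1 = a1, c1 = c1, bn2 = bn2$cache,
                    a2 = a2, stride = stride, proj = proj))
}

ru_bwd <- function(P, cache, name, dout) {
  g <- list()
  cb2 <- conv_bwd(cache$a2, P[[sprintf("%s_c2_w", name)]], dout, 1L)
  g[[sprintf("%s_c2_w", name)]] <- cb2$dw
  g[[sprintf("%s_c2_b", name)]] <- cb2$db
  da2 <- relu_bwd(cache$a2, cb2$dx)
  bb2 <- bn_bwd(cache$bn2, da2)
  g[[sprintf("%s_bn2_g", name)]] <- bb2$dgamma
  g[[sprintf("%s_bn2_b", name)]] <- bb2$dbeta
  cb1 <- conv_bwd(cache$a1, P[[sprintf("%s_c1_w", name)]], bb2$dx, cache$stride)
  g[[sprintf("%s_c1_w", name)]] <- cb1$dw
  g[[sprintf("%s_c1_b", name)]] <- cb1$db
  da1 <- relu_bwd(cache$a1, cb1$dx)
  bb1 <- bn_bwd(cache$bn1, da1)
  g[[sprintf("%s_bn1_g", name)]] <- bb1$dgamma
  g[[sprintf("%s_bn1_b", name)]] <- bb1$dbeta
  dx <- bb1$dx
  if (cache$proj) {
    pb <- conv_bwd(cache$x, P[[sprintf("%s_proj_w", name)]], dout, cache$stride)
    g[[sprintf("%s_proj_w", name)]] <- pb$dw
    g[[sprintf("%s_proj_b", name)]] <- pb$db
    dx <- dx + pb$dx
  } else {
    dx <- dx + dout
  }
  list(dx = dx, grads = g)
}

#' ResUnet denoiser
#'
#' Encoder-bridge-decoder built from pre-activation residual units
#' ((BN -> ReLU -> Conv3x3) x 2 with identity or 1x1-projection shortcut).
#' Down-sampling is a stride-2 first convolution of each encoder unit;
#' up-sampling is nearest-neighbor upsampling followed by a 3x3 convolution,
#' then concatenation with the matching encoder output. A final 1x1
#' convolution (zero-initialized) maps to one channel. Input sides must be
#' divisible by `2^length(level_filters)`.
#'
#' @param level_filters encoder filters per level (defaults 64, 128, 256).
#' @param bridge_filters filters at the bridge (default 512).
#' @param seed initialization seed.
#' @return a `dmsa_model`.
#' @export
build_resunet <- function(level_filters = c(64L, 128L, 256L),
                          bridge_filters = 512L, seed = 1L) {
  set.seed(seed)
  L <- length(level_filters)
  params <- list(); stats <- list(); n_conv <- 0L
  add <- function(unit) {
    params <<- c(params, unit$params)
    stats <<- c(stats, unit$stats)
  }
  cin <- 1L
  for (l in seq_len(L)) {
    add(ru_init(sprintf("enc%d", l), cin, level_filters[l],
                stride = if (l == 1L) 1L else 2L))
    n_conv <- n_conv + 3L   # two 3x3 convs + projection
    cin <- level_filters[l]
  }
  add(ru_init("bridge", cin, bridge_filters, stride = 2L))
  n_conv <- n_conv + 3L
  cprev <- bridge_filters
  for (l in rev(seq_len(L))) {
    up <- conv_init(3L, cprev, level_filters[l])
    params[[sprintf("up%d_w", l)]] <- up$w
    params[[sprintf("up%d_b", l)]] <- up$b
    add(ru_init(sprintf("dec%d", l), 2L * level_filters[l], level_filters[l],
                stride = 1L))
    n_conv <- n_conv + 4L   # upsample conv + unit convs
    cprev <- level_filters[l]
  }
  fin <- conv_init(1L, level_filters[1L], 1L, zero = TRUE)
  params$final_w <- fin$w; params$final_b <- fin$b
  n_conv <- n_conv + 1L
  new_model("resunet",
            list(level_filters = level_filters, bridge_filters = bridge_filters,
                 levels = L),
            params, stats, n_conv = n_conv)
}

resunet_fwd <- function(model, x, training) {
  P <- model$params
  L <- model$cfg$levels
  d <- dim(x)
  if (d[1] %% 2^L != 0L || d[2] %% 2^L != 0L)
    stop(sprintf("ResUnet input sides must be divisible by %d", 2^L))
  stats <- model$stats
  cache <- list(enc = vector("list", L), dec = vector("list", L),
                up_in = vector("list", L))
  e <- vector("list", L)
  h <- x
  for (l in seq_len(L)) {
    r <- ru_fwd(P, stats, sprintf("enc%d", l), h,
                stride = if (l == 1L) 1L else 2L, training)
    stats <- r$stats
    cache$enc[[l]] <- r$cache
    e[[l]] <- r$y
    h <- r$y
  }
  r <- ru_fwd(P, stats, "bridge", h, stride = 2L, training)
  stats <- r$stats
  cache$bridge <- r$cache
  h <- r$y
  for (l in rev(seq_len(L))) {
    up_in <- upsample2_fwd(h)
    cache$up_in[[l]] <- up_in
    u <- conv_fwd(up_in, P[[sprintf("up%d_w", l)]], P[[sprintf("up%d_b", l)]], 1L)
    cat_in <- concat_ch(e[[l]], u)
    r <- ru_fwd(P, stats, sprintf("dec%d", l), cat_in, stride = 1L, training)
    stats <- r$stats
    cache$dec[[l]] <- r$cache
    h <- r$y
  }
  out <- conv_fwd(h, P$final_w, P$final_b, 1L)
  cache$h_final <- h
  list(out = out, cache = cache, stats = stats)
}

resunet_bwd <- function(model, cache, dout) {
  P <- model$params
  L <- model$cfg$levels
  lf <- model$cfg$level_filters
  g <- list()
  fb <- conv_bwd(cache$h_final, P$final_w, dout, 1L)
  g$final_w <- fb$dw; g$final_b <- fb$db
  dh <- fb$dx
  de <- vector("list", L)   # gradients flowing into encoder outputs (skips)
  for (l in seq_len(L)) {
    r <- ru_bwd(P, cache$dec[[l]], sprintf("dec%d", l), dh)
    g <- c(g, r$grads)
    sp <- split_ch(r$dx, lf[l])
    de[[l]] <- sp[[1]]
    ub <- conv_bwd(cache$up_in[[l]], P[[sprintf("up%d_w", l)]], sp[[2]], 1L)
    g[[sprintf("up%d_w", l)]] <- ub$dw
    g[[sprintf("up%d_b", l)]] <- ub$db
    dh <- upsample2_bwd(ub$dx)
  }
  r <- ru_bwd(P, cache$bridge, "bridge", dh)
  g <- c(g, r$grads)
  dh <- r$dx
  for (l in rev(seq_len(L))) {
    dh <- dh + de[[l]]
    r <- ru_bwd(P, cache$enc[[l]], sprintf("enc%d", l), dh)
    g <- c(g, r$grads)
    dh <- r$dx
  }
  g
}

# ---- Generic forward / backward -------------------------------------------

#' Forward pass of a model
#'
#' @param model a `dmsa_model`.
#' @param x input tensor `(H, W, 1, N)` or a single matrix, standardized.
#' @param training use batch statistics and update running statistics
#'   (`TRUE`) or frozen running statistics (`FALSE`).
#' @return `list(out, cache, stats)`; assign `stats` back to the model when
#'   training.
#' @export
model_forward <- function(model, x, training = FALSE) {
  x <- as_tensor(x)
  switch(model$arch,
         dncnn = dncnn_fwd(model, x, training),
         win5rb = win5rb_fwd(model, x, training),
         resunet = resunet_fwd(model, x, training))
}

#' Backward pass of a model
#'
#' @param model a `dmsa_model`.
#' @param cache forward cache from [model_forward()] (training mode).
#' @param dout gradient of the loss with respect to the output.
#' @return named list of parameter gradients.
#' @export
model_backward <- function(model, cache, dout) {
  switch(model$arch,
         dncnn = dncnn_bwd(model, cache, dout),
         win5rb = win5rb_bwd(model, cache, dout),
         resunet = resunet_bwd(model, cache, dout))
}

#' Save / load a model
#'
#' Writes the weights plus a JSON architecture manifest so checkpoints are
#' self-describing; loading reproduces bit-identical forward outputs.
#'
#' @param model a `dmsa_model`.
#' @param path file path for the checkpoint (`.rds`); the manifest is
#'   written alongside with extension `.json`.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(list(arch = model$arch, cfg = model$cfg,
                            n_conv_layers = model$n_conv,
                            n_params = n_params(model)),
                       sub("\\.rds$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
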