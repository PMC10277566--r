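# Minimal feed-forward engine for the EEG backbones.
#
# Activations travel as R arrays with dim (N, C, H, W). For raw epochs the
# single input map holds electrodes on H and time on W, i.e. dim
# (trials, 1, channels, samples). All randomness (weight init, shuffling,
# dropout) draws from R's RNG so a single set.seed() makes training
# reproducible.

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- layer constructors ----------------------------------------------------

nn_conv <- function(in_ch, out_ch, kh, kw, pad_h = 0L, pad_w = 0L,
                    groups = 1L, bias = TRUE, max_norm = NULL) {
  stopifnot(in_ch %% groups == 0, out_ch %% groups == 0)
  fan_in <- (in_ch / groups) * kh * kw
  fan_out <- (out_ch / groups) * kh * kw
  lim <- sqrt(6 / (fan_in + fan_out))  # Glorot uniform
  W <- array(stats::runif(out_ch * (in_ch / groups) * kh * kw, -lim, lim),
             dim = c(out_ch, in_ch / groups, kh, kw))
  list(type = "conv", W = W, b = if (bias) numeric(out_ch) else NULL,
       pad_h = as.integer(pad_h), pad_w = as.integer(pad_w),
       groups = as.integer(groups), max_norm = max_norm)
}

nn_bn <- function(ch, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", gamma = rep(1, ch), beta = numeric(ch),
       run_mean = numeric(ch), run_var = rep(1, ch),
       eps = eps, momentum = momentum)
}

nn_act <- function(fun = c("elu", "square", "safelog")) {
  list(type = "act", fun = match.arg(fun))
}

nn_pool <- function(mode = c("avg", "max"), kh, kw, sh = kh, sw = kw) {
  list(type = "pool", mode = match.arg(mode),
       kh = as.integer(kh), kw = as.integer(kw),
       sh = as.integer(sh), sw = as.integer(sw))
}

nn_dropout <- function(p) list(type = "dropout", p = p)

## ---- forward / backward ----------------------------------------------------

layer_forward <- function(layer, x, training = FALSE) {
  cache <- NULL
  switch(layer$type,
    conv = {
      y <- conv2d_fwd(x, layer$W, layer$b %||% numeric(0),
                      layer$pad_h, layer$pad_w, layer$groups)
      cache <- list(x = x)
    },
    bn = {
      # per-channel statistics over (N, H, W), computed on the (N*C, H*W)
      # reshape; rows of that matrix are indexed by (n, c) with n fastest
      d <- dim(x)
      N <- d[1]; ch <- d[2]; M <- d[1] * d[3] * d[4]
      xm <- x
      dim(xm) <- c(N * ch, d[3] * d[4])
      if (training) {
        mu <- colSums(matrix(rowSums(xm), N, ch)) / M
        xc <- xm - rep(mu, each = N)
        vv <- colSums(matrix(rowSums(xc * xc), N, ch)) / M
        invstd <- 1 / sqrt(vv + layer$eps)
        xhat <- xc * rep(invstd, each = N)
        y <- xhat * rep(layer$gamma, each = N) + rep(layer$beta, each = N)
        dim(y) <- d
        dim(xhat) <- d
        layer$run_mean <- (1 - layer$momentum) * layer$run_mean +
          layer$momentum * mu
        layer$run_var <- (1 - layer$momentum) * layer$run_var +
          layer$momentum * vv
        cache <- list(xhat = xhat, invstd = invstd)
      } else {
        sc <- layer$gamma / sqrt(layer$run_var + layer$eps)
        y <- (xm - rep(layer$run_mean, each = N)) * rep(sc, each = N) +
          rep(layer$beta, each = N)
        dim(y) <- d
      }
    },
    act = {
      y <- switch(layer$fun,
        elu = { z <- x; neg <- x < 0; z[neg] <- expm1(x[neg]); z },
        square = x * x,
        safelog = log(pmax(x, 1e-7)))
      cache <- list(x = x, y = y)
    },
    pool = {
      p <- pool2d_fwd(x, layer$kh, layer$kw, layer$sh, layer$sw,
                      layer$mode == "max")
      y <- p$y
      cache <- list(xdim = dim(x), argmax = p$argmax)
    },
    dropout = {
      if (training && layer$p > 0) {
        keep <- (stats::runif(length(x)) >= layer$p) / (1 - layer$p)
        y <- x * keep
        dim(y) <- dim(x)
        cache <- list(keep = keep)
      } else {
        y <- x
      }
    },
    stop("unknown layer type: ", layer$type))
  list(y = y, cache = cache, layer = layer)
}

layer_backward <- function(layer, cache, gy) {
  grads <- NULL
  switch(layer$type,
    conv = {
      bw <- conv2d_bwd(cache$x, layer$W, gy,
                       layer$pad_h, layer$pad_w, layer$groups, TRUE)
      gx <- bw$gx
      grads <- list(W = bw$gw, b = if (is.null(layer$b)) NULL else bw$gb)
    },
    bn = {
      d <- dim(gy)
      N <- d[1]; ch <- d[2]; M <- d[1] * d[3] * d[4]
      gm <- gy; dim(gm) <- c(N * ch, d[3] * d[4])
      xh <- cache$xhat; dim(xh) <- c(N * ch, d[3] * d[4])
      gbeta <- colSums(matrix(rowSums(gm), N, ch))
      ggamma <- colSums(matrix(rowSums(gm * xh), N, ch))
      sc <- layer$gamma * cache$invstd / M
      gx <- rep(sc, each = N) *
        (M * gm - rep(gbeta, each = N) - xh * rep(ggamma, each = N))
      dim(gx) <- d
      grads <- list(gamma = ggamma, beta = gbeta)
    },
    act = {
      gx <- switch(layer$fun,
        elu = { pos <- cache$x > 0; gy * (pos + (!pos) * (cache$y + 1)) },
        square = gy * 2 * cache$x,
        safelog = gy / pmax(cache$x, 1e-7))
      dim(gx) <- dim(gy)
    },
    pool = {
      gx <- pool2d_bwd(gy, as.integer(cache$xdim), layer$kh, layer$kw,
                       layer$sh, layer$sw, layer$mode == "max",
                       cache$argmax %||% integer(0))
    },
    dropout = {
      if (is.null(cache)) {
        gx <- gy
      } else {
        gx <- gy * cache$keep
        dim(gx) <- dim(gy)
      }
    })
  list(gx = gx, grads = grads)
}

net_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    st <- layer_forward(layers[[i]], x, training)
    x <- st$y
    caches[[i]] <- st$cache
    layers[[i]] <- st$layer
  }
  list(y = x, caches = caches, layers = layers)
}

net_backward <- function(layers, caches, gy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    st <- layer_backward(layers[[i]], caches[[i]], gy)
    gy <- st$gx
    grads[i] <- list(st$grads)  # keep NULL entries (no-parameter layers)
  }
  list(gx = gy, grads = grads)
}

## ---- optimizers ------------------------------------------------------------

opt_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

opt_step <- function(p, g, st, lr, cfg, t) {
  if (cfg$optimizer == "adam") {
    st$m <- 0.9 * st$m + 0.1 * g
    st$v <- 0.999 * st$v + 0.001 * g * g
    mhat <- st$m / (1 - 0.9^t)
    vhat <- st$v / (1 - 0.999^t)
    p <- p - lr * mhat / (sqrt(vhat) + 1e-8)
  } else if (cfg$optimizer == "rmsprop") {
    st$v <- 0.99 * st$v + 0.01 * g * g
    p <- p - lr * g / (sqrt(st$v) + 1e-8)
  } else stop("unknown optimizer: ", cfg$optimizer)
  list(p = p, st = st)
}

sched_lr <- function(cfg, epoch) {
  switch(cfg$scheduler,
    cosine = cfg$lr * 0.5 * (1 + cos(pi * (epoch - 1) / cfg$epochs)),
    exponential = cfg$lr * cfg$gamma^(epoch - 1),
    none = cfg$lr,
    stop("unknown scheduler: ", cfg$scheduler))
}

# renormalize filters / columns whose L2 norm exceeds max_norm
apply_max_norm <- function(W, max_norm, axis = c("filter", "column")) {
  axis <- match.arg(axis)
  if (axis == "filter") {
    d <- dim(W)
    Wm <- matrix(W, nrow = d[1])
    nr <- sqrt(rowSums(Wm^2))
    sc <- pmin(1, max_norm / pmax(nr, 1e-12))
    Wm <- Wm * sc
    array(Wm, dim = d)
  } else {
    nr <- sqrt(colSums(W^2))
    sc <- pmin(1, max_norm / pmax(nr, 1e-12))
    sweep(W, 2, sc, `*`)
  }
}

softmax_rows <- function(s) {
  s <- s - apply(s, 1, max)
  e <- exp(s)
  e / rowSums(e)
}

cross_entropy <- function(scores, y) {
  p <- softmax_rows(scores)
  n <- nrow(scores)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y + 1L)], 1e-300)))
  g <- p
  g[cbind(seq_len(n), y + 1L)] <- g[cbind(seq_len(n), y + 1L)] - 1
  list(loss = loss, gscores = g / n)
}
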