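# The three standard EEG decoding backbones, each split into a convolutional
# feature extractor F and a single dense classifier C on the flattened
# feature map. Architectures follow the original publications (filter counts,
# pooling modes, activations); temporal kernels are kept odd so same-padding
# preserves the time dimension exactly.

eegnet_layers <- function(n_channels, sfreq, F1 = 8, D = 2, F2 = 16,
                          dropout = 0.5) {
  kt <- round(sfreq / 2)                  # temporal kernel = half the rate
  if (kt %% 2 == 0) kt <- kt + 1
  list(
    nn_conv(1, F1, 1, kt, pad_w = (kt - 1) / 2, bias = FALSE),
    nn_bn(F1),
    nn_conv(F1, F1 * D, n_channels, 1, groups = F1, bias = FALSE,
            max_norm = 1),               # depthwise spatial filter
    nn_bn(F1 * D),
    nn_act("elu"),
    nn_pool("avg", 1, 4),
    nn_dropout(dropout),
    nn_conv(F1 * D, F1 * D, 1, 15, pad_w = 7, groups = F1 * D, bias = FALSE),
    nn_conv(F1 * D, F2, 1, 1, bias = FALSE),  # separable = depthwise + 1x1
    nn_bn(F2),
    nn_act("elu"),
    nn_pool("avg", 1, 8),
    nn_dropout(dropout)
  )
}

shallowconvnet_layers <- function(n_channels, sfreq, n_filters = 40,
                                  dropout = 0.5) {
  list(
    nn_conv(1, n_filters, 1, 25),
    nn_conv(n_filters, n_filters, n_channels, 1, bias = FALSE),
    nn_bn(n_filters),
    nn_act("square"),
    nn_pool("avg", 1, 75, 1, 15),
    nn_act("safelog"),
    nn_dropout(dropout)
  )
}

deepconvnet_layers <- function(n_channels, sfreq, dropout = 0.5) {
  blk <- function(cin, cout, first = FALSE) {
    c(if (first) list(nn_conv(1, cout, 1, 10),
                      nn_conv(cout, cout, n_channels, 1, bias = FALSE))
      else list(nn_conv(cin, cout, 1, 10)),
      list(nn_bn(cout), nn_act("elu"), nn_pool("max", 1, 3),
           nn_dropout(dropout)))
  }
  c(blk(1, 25, first = TRUE), blk(25, 50), blk(50, 100), blk(100, 200))
}

backbone_builders <- list(
  eegnet = eegnet_layers,
  shallowconvnet = shallowconvnet_layers,
  deepconvnet = deepconvnet_layers
)

# shape of F's output for a given input size, from a dummy eval-mode pass
infer_feature_shape <- function(layers, n_channels, n_samples) {
  x <- array(0, dim = c(1, 1, n_channels, n_samples))
  y <- net_forward(layers, x, training = FALSE)$y
  dim(y)[-1]
}

#' Build an EEG decoding backbone
#'
#' Constructs one of the three standard convolutional backbones with an
#' explicit extractor/classifier split: `F` is the convolutional stack up to
#' the flattened feature map, `C` a single dense layer mapping the feature
#' map to class scores. EEGNet's temporal kernel length is half the sampling
#' rate (e.g. 1 x 125 at 250 Hz) and its depthwise spatial kernel spans all
#' channels (e.g. 22 x 1); DeepConvNet has four convolution blocks with
#' max-pooling, ShallowConvNet two blocks with average pooling and
#' square/log activations.
#'
#' @param name one of `"eegnet"`, `"deepconvnet"`, `"shallowconvnet"`.
#' @param n_channels,n_samples input epoch dimensions.
#' @param n_classes number of output classes.
#' @param sfreq sampling rate in Hz (sets EEGNet's temporal kernel).
#' @param ... architecture overrides passed to the builder (e.g. `F1`, `D`,
#'   `F2`, `dropout` for EEGNet).
#' @return A `backbone_model` (untrained; [train_backbone()] re-initializes
#'   parameters under its own seed).
#' @export
build_backbone <- function(name, n_channels, n_samples, n_classes, sfreq, ...) {
  if (!name %in% names(backbone_builders))
    stop("unknown backbone '", name, "'; available: ",
         paste(names(backbone_builders), collapse = ", "))
  build_args <- list(n_channels = n_channels, sfreq = sfreq, ...)
  model <- with_seed(0, {
    layers <- do.call(backbone_builders[[name]], build_args)
    fs <- infer_feature_shape(layers, n_channels, n_samples)
    nf <- prod(fs)
    lim <- sqrt(6 / (nf + n_classes))
    list(layers = layers,
         W = matrix(stats::runif(nf * n_classes, -lim, lim), nf, n_classes),
         b = numeric(n_classes))
  })
  structure(list(name = name, layers = model$layers,
                 W = model$W, b = model$b,
                 feature_shape = infer_feature_shape(model$layers,
                                                     n_channels, n_samples),
                 n_feat = nrow(model$W), n_classes = n_classes,
                 n_channels = n_channels, n_samples = n_samples,
                 sfreq = sfreq, build_args = build_args,
                 dense_max_norm = if (name == "eegnet") 0.25 else NULL,
                 trained = FALSE, seed = NA_integer_, history = NULL),
            class = "backbone_model")
}

#' @export
print.backbone_model <- function(x, ...) {
  cat(sprintf(
    "<backbone_model %s> input %d x %d, feature map %s (%d positions), %d classes%s\n",
    x$name, x$n_channels, x$n_samples,
    paste(x$feature_shape, collapse = "x"), x$n_feat, x$n_classes,
    if (x$trained) sprintf(", trained (seed %d)", x$seed) else " (untrained)"))
  invisible(x)
}

#' Training configuration
#'
#' Two presets mirror common MI settings: `"adam_cosine"` (Adam, lr 0.002,
#' cosine annealing, batch 72) and `"rmsprop_exp"` (RMSProp, lr 0.001,
#' exponential decay, batch 5).
#'
#' @param optimizer `"adam"` or `"rmsprop"`.
#' @param lr learning rate.
#' @param scheduler `"cosine"`, `"exponential"` or `"none"`.
#' @param batch_size minibatch size.
#' @param epochs number of passes over the training set.
#' @param seed integer seed controlling initialization, shuffling and dropout.
#' @param gamma decay factor of the exponential scheduler.
#' @param preset optional preset name applied before the other arguments.
#' @return A `train_config` list.
#' @export
train_config <- function(optimizer = "adam", lr = 0.002, scheduler = "cosine",
                         batch_size = 72, epochs = 200, seed = 1,
                         gamma = 0.99, preset = NULL) {
  cfg <- list(optimizer = optimizer, lr = lr, scheduler = scheduler,
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), seed = as.integer(seed),
              gamma = gamma)
  if (!is.null(preset)) {
    if (preset == "rmsprop_exp") {
      cfg$optimizer <- "rmsprop"; cfg$lr <- 0.001
      cfg$scheduler <- "exponential"; cfg$batch_size <- 5L
    } else if (preset != "adam_cosine") stop("unknown preset: ", preset)
  }
  # NA batch size is resolved by the consumer (retraining uses n/4);
  # epochs = 0 is allowed for "no update" retraining
  if (!is.na(cfg$batch_size) && cfg$batch_size < 1)
    stop("batch_size must be >= 1")
  if (cfg$epochs < 0) stop("epochs must be >= 0")
  structure(cfg, class = "train_config")
}

epochs_to_input <- function(ep) {
  d <- dim(ep$data)
  x <- ep$data
  dim(x) <- c(d[1], 1L, d[2], d[3])
  x
}

# one optimizer update over every trainable parameter of the model
update_params <- function(model, grads_F, gW, gb, states, lr, cfg, t) {
  for (i in seq_along(model$layers)) {
    g <- grads_F[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      if (is.null(g[[nm]])) next
      key <- paste0("L", i, ".", nm)
      st <- opt_step(model$layers[[i]][[nm]], g[[nm]], states[[key]],
                     lr, cfg, t)
      model$layers[[i]][[nm]] <- st$p
      states[[key]] <- st$st
    }
    mn <- model$layers[[i]]$max_norm
    if (!is.null(mn))
      model$layers[[i]]$W <- apply_max_norm(model$layers[[i]]$W, mn, "filter")
  }
  st <- opt_step(model$W, gW, states$CW, lr, cfg, t)
  model$W <- st$p; states$CW <- st$st
  st <- opt_step(model$b, gb, states$Cb, lr, cfg, t)
  model$b <- st$p; states$Cb <- st$st
  if (!is.null(model$dense_max_norm))
    model$W <- apply_max_norm(model$W, model$dense_max_norm, "column")
  list(model = model, states = states)
}

init_opt_states <- function(model) {
  states <- list()
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    for (nm in intersect(c("W", "b", "gamma", "beta"), names(l))) {
      if (is.null(l[[nm]])) next
      if (l$type %in% c("conv") && nm %in% c("W", "b") ||
          l$type == "bn" && nm %in% c("gamma", "beta"))
        states[[paste0("L", i, ".", nm)]] <- list(m = l[[nm]] * 0,
                                                  v = l[[nm]] * 0)
    }
  }
  states$CW <- list(m = model$W * 0, v = model$W * 0)
  states$Cb <- list(m = model$b * 0, v = model$b * 0)
  states
}

#' Train a backbone end to end
#'
#' Jointly optimizes the feature extractor F and classifier C with softmax
#' cross-entropy. All randomness (re-initialization, shuffling, dropout)
#' derives from `cfg$seed`, so a fixed seed reproduces the final parameters
#' bit for bit.
#'
#' @param model a [build_backbone()] model.
#' @param train an [epoch_set()]; every class in `0..n_classes-1` must occur.
#' @param cfg a [train_config()].
#' @return The trained `backbone_model` with a `history` of per-epoch mean
#'   training losses.
#' @export
train_backbone <- function(model, train, cfg = train_config()) {
  stopifnot(inherits(model, "backbone_model"), inherits(train, "epoch_set"))
  y <- train$labels
  if (any(y < 0 | y >= model$n_classes))
    stop("labels must lie in [0, n_classes)")
  if (length(unique(y)) < model$n_classes)
    stop("every class must be present in the training set")
  x <- epochs_to_input(train)
  n <- dim(x)[1]

  with_seed(cfg$seed, {
    # fresh seeded initialization so cfg$seed fully determines the run
    fresh <- do.call(backbone_builders[[model$name]], model$build_args)
    model$layers <- fresh
    lim <- sqrt(6 / (model$n_feat + model$n_classes))
    model$W <- matrix(stats::runif(model$n_feat * model$n_classes, -lim, lim),
                      model$n_feat, model$n_classes)
    model$b <- numeric(model$n_classes)

    states <- init_opt_states(model)
    t_step <- 0
    history <- numeric(cfg$epochs)
    for (e in seq_len(cfg$epochs)) {
      lr <- sched_lr(cfg, e)
      idx <- sample.int(n)
      losses <- c()
      for (b0 in seq(1, n, by = cfg$batch_size)) {
        bi <- idx[b0:min(b0 + cfg$batch_size - 1, n)]
        xb <- x[bi, , , , drop = FALSE]
        yb <- y[bi]
        fw <- net_forward(model$layers, xb, training = TRUE)
        model$layers <- fw$layers          # BN running stats
        feat <- matrix(fw$y, nrow = length(bi))
        scores <- feat %*% model$W + rep(model$b, each = length(bi))
        ce <- cross_entropy(scores, yb)
        losses <- c(losses, ce$loss)
        gW <- t(feat) %*% ce$gscores
        gb <- colSums(ce$gscores)
        gfeat <- ce$gscores %*% t(model$W)
        dim(gfeat) <- dim(fw$y)
        bw <- net_backward(model$layers, fw$caches, gfeat)
        t_step <- t_step + 1
        up <- update_params(model, bw$grads, gW, gb, states, lr, cfg, t_step)
        model <- up$model; states <- up$states
      }
      history[e] <- mean(losses)
    }
    model$history <- history
    model$trained <- TRUE
    model$seed <- cfg$seed
    model
  })
}

#' Extract the feature map for a set of epochs
#'
#' Deterministic evaluation-mode forward pass of the extractor F only
#' (dropout off, batch-norm uses frozen running statistics).
#'
#' @param model a trained [build_backbone()] model.
#' @param epochs an [epoch_set()] matching the model's input shape.
#' @return A `feature_tensor`: list with `values` (trials x positions matrix,
#'   positions in feature-map order), `feature_shape`, `labels`, `trial_ids`.
#' @export
extract_features <- function(model, epochs) {
  stopifnot(inherits(model, "backbone_model"), inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  if (d[2] != model$n_channels || d[3] != model$n_samples)
    stop(sprintf("epoch shape %d x %d does not match model input %d x %d",
                 d[2], d[3], model$n_channels, model$n_samples))
  x <- epochs_to_input(epochs)
  y <- net_forward(model$layers, x, training = FALSE)$y
  if (any(!is.finite(y))) stop("non-finite feature values")
  structure(list(values = matrix(y, nrow = d[1]),
                 feature_shape = model$feature_shape,
                 labels = epochs$labels, trial_ids = seq_len(d[1])),
            class = "feature_tensor")
}

#' Stand-alone dense classifier over a feature table
#'
#' A `backbone_model` with an empty (identity) extractor: the "feature map"
#' is the feature vector itself. Useful for running the LRP scoring and
#' selection machinery on plain feature tables. Train it with
#' [retrain_classifier()] (`warm_start = FALSE` for a fresh fit).
#'
#' @param n_features number of input features.
#' @param n_classes number of classes.
#' @return A `backbone_model` whose classifier C is the whole model.
#' @export
dense_classifier <- function(n_features, n_classes) {
  W <- with_seed(0, {
    lim <- sqrt(6 / (n_features + n_classes))
    matrix(stats::runif(n_features * n_classes, -lim, lim),
           n_features, n_classes)
  })
  structure(list(name = "dense", layers = list(), W = W,
                 b = numeric(n_classes),
                 feature_shape = c(n_features, 1L, 1L),
                 n_feat = n_features, n_classes = n_classes,
                 n_channels = NA_integer_, n_samples = NA_integer_,
                 sfreq = NA_real_, build_args = NULL, dense_max_norm = NULL,
                 trained = FALSE, seed = NA_integer_, history = NULL),
            class = "backbone_model")
}

#' Wrap a plain matrix as a feature tensor
#'
#' @param x samples x features matrix.
#' @param labels optional 0-based labels.
#' @return A `feature_tensor`.
#' @export
as_feature_tensor <- function(x, labels = NULL) {
  x <- as.matrix(x)
  structure(list(values = x, feature_shape = c(ncol(x), 1L, 1L),
                 labels = if (!is.null(labels)) as.integer(labels),
                 trial_ids = seq_len(nrow(x))),
            class = "feature_tensor")
}

#' Class scores and labels from extracted features
#'
#' Applies the dense classifier C to (optionally masked) features:
#' `scores = C(features * keep)`. With `mask = NULL` this is exactly the
#' full model's forward pass restricted to C.
#'
#' @param model a `backbone_model`.
#' @param features a `feature_tensor` from [extract_features()], or a plain
#'   trials x positions matrix.
#' @param mask optional [build_mask()] result applied before C.
#' @return list with `scores` (trials x classes, pre-softmax) and `labels`
#'   (0-based argmax predictions).
#' @export
predict_backbone <- function(model, features, mask = NULL) {
  feat <- if (inherits(features, "feature_tensor")) features$values
          else as.matrix(features)
  if (ncol(feat) != model$n_feat)
    stop("feature width does not match the classifier input size")
  if (!is.null(mask)) {
    if (length(mask$keep) != model$n_feat)
      stop("mask length does not match the feature map")
    feat <- sweep(feat, 2, as.numeric(mask$keep), `*`)
  }
  scores <- feat %*% model$W + rep(model$b, each = nrow(feat))
  list(scores = scores, labels = max.col(scores, ties.method = "first") - 1L)
}
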