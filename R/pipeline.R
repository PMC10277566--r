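# Orchestration of the three-step framework per subject and seed:
# (A) train the backbone, (B) score the feature map with LRP (or a baseline
# selector) on training trials and mask the lowest-importance fraction,
# (C) retrain the dense classifier on masked features with the extractor
# frozen. The mask is computed from the training session only; test data are
# touched solely at evaluation.

#' Experiment run specification
#'
#' @param backbone backbone name (see [build_backbone()]).
#' @param selector `"lrp"`, `"anova"`, `"mrmr"`, `"rfe"` or `"none"`
#'   (backbone-only evaluation).
#' @param mask_fraction fraction of lowest-importance feature-map positions
#'   masked before retraining (the reference setting is 0.10).
#' @param backbone_cfg [train_config()] for backbone training (its seed is
#'   overridden per run seed).
#' @param retrain_cfg [train_config()] for classifier retraining; a `NULL`
#'   batch size is replaced by one quarter of the training-set size.
#' @param seeds integer vector of run seeds (averaged in the evaluation).
#' @param lrp lrp [lrp_config()] used when `selector = "lrp"`.
#' @param aggregate relevance aggregation for [aggregate_importance()].
#' @param warm_start warm-start C from its backbone-trained weights when
#'   retraining (`TRUE`, the default) or re-initialize it.
#' @return A `run_spec` list.
#' @export
run_spec <- function(backbone = "eegnet", selector = "lrp",
                     mask_fraction = 0.1,
                     backbone_cfg = train_config(epochs = 200),
                     retrain_cfg = train_config(epochs = 100,
                                                batch_size = NA),
                     seeds = 1:5, lrp = lrp_config(),
                     aggregate = "abs_mean", warm_start = TRUE) {
  if (length(seeds) == 0) stop("seeds must be nonempty")
  if (mask_fraction < 0 || mask_fraction > 1)
    stop("mask_fraction must be in [0, 1]")
  if (!selector %in% c("lrp", "anova", "mrmr", "rfe", "none"))
    stop("unknown selector: ", selector)
  structure(list(backbone = backbone, selector = selector,
                 mask_fraction = mask_fraction,
                 backbone_cfg = backbone_cfg, retrain_cfg = retrain_cfg,
                 seeds = as.integer(seeds), lrp = lrp,
                 aggregate = aggregate, warm_start = warm_start),
            class = "run_spec")
}

# order-insensitive but value-exact digest of the extractor parameters;
# used to verify the freeze contract bitwise
extractor_checksum <- function(model) {
  raw <- serialize(lapply(model$layers, function(l)
    l[intersect(c("W", "b", "gamma", "beta", "run_mean", "run_var"),
                names(l))]), NULL, version = 2)
  sum(as.double(raw) * seq_along(raw))
}

#' Retrain the classifier on masked features with a frozen extractor
#'
#' Only C's dense parameters are updated; F is untouched (verified by a
#' parameter checksum before/after — any change is a hard failure). C
#' warm-starts from its backbone-trained weights unless `warm_start = FALSE`.
#' With `cfg$epochs = 0` the classifier is returned unchanged.
#'
#' @param model a trained `backbone_model`.
#' @param masked_features a `feature_tensor` (already masked) or matrix.
#' @param labels 0-based labels (taken from the feature tensor if absent).
#' @param cfg a [train_config()]; `NA` batch size means a quarter of the
#'   training-set size.
#' @param warm_start keep C's current weights as the starting point.
#' @return The model with retrained C.
#' @export
retrain_classifier <- function(model, masked_features, labels = NULL,
                               cfg = train_config(epochs = 100,
                                                  batch_size = NA),
                               warm_start = TRUE) {
  feat <- feature_matrix_of(masked_features)
  y <- labels %||% masked_features$labels
  if (is.null(y)) stop("labels required")
  n <- nrow(feat)
  if (is.na(cfg$batch_size)) cfg$batch_size <- max(1L, n %/% 4L)
  ck_before <- extractor_checksum(model)
  model <- with_seed(cfg$seed, {
    if (!warm_start) {
      lim <- sqrt(6 / (model$n_feat + model$n_classes))
      model$W <- matrix(stats::runif(model$n_feat * model$n_classes,
                                     -lim, lim),
                        model$n_feat, model$n_classes)
      model$b <- numeric(model$n_classes)
    }
    if (cfg$epochs > 0) {
      states <- list(CW = list(m = model$W * 0, v = model$W * 0),
                     Cb = list(m = model$b * 0, v = model$b * 0))
      t_step <- 0
      for (e in seq_len(cfg$epochs)) {
        lr <- sched_lr(cfg, e)
        idx <- sample.int(n)
        for (b0 in seq(1, n, by = cfg$batch_size)) {
          bi <- idx[b0:min(b0 + cfg$batch_size - 1, n)]
          fb <- feat[bi, , drop = FALSE]
          ce <- cross_entropy(fb %*% model$W +
                                rep(model$b, each = length(bi)), y[bi])
          st <- opt_step(model$W, t(fb) %*% ce$gscores, states$CW,
                         lr, cfg, t_step + 1)
          model$W <- st$p; states$CW <- st$st
          st <- opt_step(model$b, colSums(ce$gscores), states$Cb,
                         lr, cfg, t_step + 1)
          model$b <- st$p; states$Cb <- st$st
          t_step <- t_step + 1
          if (!is.null(model$dense_max_norm))
            model$W <- apply_max_norm(model$W, model$dense_max_norm,
                                      "column")
        }
      }
    }
    model
  })
  if (!identical(ck_before, extractor_checksum(model)))
    stop("freeze contract violated: extractor parameters changed")
  model
}

# shared step A/B of one seeded run: trained backbone, train/test features,
# importance profile per the selector (or NULL for selector = "none")
run_seed_core <- function(train, test, spec, seed) {
  n_classes <- max(train$labels, test$labels) + 1L
  d <- dim(train$data)
  model <- build_backbone(spec$backbone, d[2], d[3], n_classes, train$sfreq)
  bcfg <- spec$backbone_cfg
  bcfg$seed <- seed
  model <- train_backbone(model, train, bcfg)
  ftr_train <- extract_features(model, train)
  ftr_test <- extract_features(model, test)
  profile <- switch(spec$selector,
    none = NULL,
    lrp = aggregate_importance(
      propagate_to_feature_map(model, ftr_train, spec$lrp),
      spec$aggregate),
    anova = anova_importance(ftr_train),
    mrmr = mrmr_importance(ftr_train,
                           n_keep = model$n_feat -
                             floor(spec$mask_fraction * model$n_feat)),
    rfe = rfe_importance(ftr_train,
                         n_keep = model$n_feat -
                           floor(spec$mask_fraction * model$n_feat)))
  list(model = model, ftr_train = ftr_train, ftr_test = ftr_test,
       profile = profile, n_classes = n_classes)
}

# step C for one mask: retrain C on masked training features, evaluate on
# masked test features
retrain_and_eval <- function(core, mask, test_labels, spec, seed) {
  rcfg <- spec$retrain_cfg
  rcfg$seed <- seed
  model2 <- retrain_classifier(core$model,
                               apply_mask(core$ftr_train, mask),
                               core$ftr_train$labels, rcfg,
                               warm_start = spec$warm_start)
  pred <- predict_backbone(model2, core$ftr_test, mask)
  list(acc = accuracy(pred$labels, test_labels),
       conf = confusion(pred$labels, test_labels, core$n_classes))
}

#' Run one subject through the full framework
#'
#' For every seed: train the backbone on the training session, extract
#' features, compute the selector's importance profile on training trials,
#' mask the lowest-importance fraction, retrain C frozen-extractor on masked
#' training features, and evaluate masked predictions on the test session.
#' `selector = "none"` evaluates the backbone alone.
#'
#' @param train,test [epoch_set()]s of the training and test sessions.
#' @param spec a [run_spec()].
#' @param subject subject identifier carried into the result.
#' @return An `eval_result` (retrained accuracies; backbone-only per-seed
#'   accuracies in `$backbone_accuracies`, the last seed's mask in `$mask`).
#' @export
run_subject <- function(train, test, spec = run_spec(), subject = "S01") {
  stopifnot(inherits(train, "epoch_set"), inherits(test, "epoch_set"))
  accs <- backbone_accs <- numeric(length(spec$seeds))
  conf <- NULL
  mask <- NULL
  for (i in seq_along(spec$seeds)) {
    s <- spec$seeds[i]
    core <- run_seed_core(train, test, spec, s)
    bpred <- predict_backbone(core$model, core$ftr_test)
    backbone_accs[i] <- accuracy(bpred$labels, test$labels)
    if (spec$selector == "none") {
      accs[i] <- backbone_accs[i]
      ci <- confusion(bpred$labels, test$labels, core$n_classes)
    } else {
      mask <- build_mask(core$profile, spec$mask_fraction)
      re <- retrain_and_eval(core, mask, test$labels, spec, s)
      accs[i] <- re$acc
      ci <- re$conf
    }
    conf <- if (is.null(conf)) ci else conf + ci
  }
  eval_result(subject,
              if (spec$selector == "none") "backbone" else spec$selector,
              accs, conf,
              extra = list(backbone_accuracies = backbone_accs, mask = mask,
                           seeds = spec$seeds))
}

#' Bottom-only / top-only / proposed control experiment
#'
#' Per seed, from a single trained backbone and LRP profile, retrains three
#' classifiers: one keeping only the bottom-`fraction` feature positions
#' (lowest importance), one keeping only the top-`fraction`, and the
#' proposed variant masking the bottom `fraction` (keeping the rest). On
#' balanced multi-class data the bottom-only classifier is expected near
#' chance while top-only and proposed exceed it.
#'
#' @param train,test [epoch_set()]s.
#' @param spec a [run_spec()] with `selector = "lrp"`; `mask_fraction` is the
#'   `fraction` above.
#' @param subject subject identifier.
#' @return Named list of three `eval_result`s: `bottom_only`, `top_only`,
#'   `proposed`.
#' @export
extremes_experiment <- function(train, test, spec = run_spec(),
                                subject = "S01") {
  if (spec$selector != "lrp")
    stop("extremes_experiment requires selector = 'lrp'")
  n_seeds <- length(spec$seeds)
  acc <- matrix(0, n_seeds, 3,
                dimnames = list(NULL, c("bottom_only", "top_only",
                                        "proposed")))
  confs <- vector("list", 3)
  for (i in seq_along(spec$seeds)) {
    s <- spec$seeds[i]
    core <- run_seed_core(train, test, spec, s)
    scores <- core$profile$scores
    N <- length(scores)
    m <- floor(spec$mask_fraction * N)
    masks <- list(
      bottom_only = build_mask(-scores, (N - m) / N),  # keep lowest m
      top_only = build_mask(scores, (N - m) / N),      # keep highest m
      proposed = build_mask(scores, spec$mask_fraction))
    for (j in seq_len(3)) {
      re <- retrain_and_eval(core, masks[[j]], test$labels, spec, s)
      acc[i, j] <- re$acc
      confs[[j]] <- if (is.null(confs[[j]])) re$conf else confs[[j]] + re$conf
    }
  }
  out <- lapply(seq_len(3), function(j)
    eval_result(subject, colnames(acc)[j], acc[, j], confs[[j]],
                extra = list(seeds = spec$seeds)))
  names(out) <- colnames(acc)
  out
}
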