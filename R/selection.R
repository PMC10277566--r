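# Turning importance scores into a single feature mask and applying it, plus
# the classical baseline selectors (ANOVA F, mRMR, RFE). One fixed mask per
# (subject, backbone, seed) is computed from training-session data only and
# applied unchanged to test trials.

#' Aggregate per-trial relevance into one importance profile
#'
#' Position-wise aggregate of training-trial relevance. The default
#' `abs_mean` first averages the signed relevance over trials (noise
#' contributions cancel) and then takes the magnitude, so "low importance"
#' means a near-zero aggregate — class-irrelevant positions — while strong
#' evidence of either sign ranks high. `mean_signed` keeps the signed
#' average itself (the quantity shown in relevance heatmaps; the most
#' counter-evidential positions rank lowest), and `mean_abs` averages the
#' per-trial magnitudes.
#'
#' @param relevance a `relevance_map` over training trials.
#' @param method `"abs_mean"`, `"mean_signed"` or `"mean_abs"`.
#' @return An `importance_profile`: list with `scores` (one per feature-map
#'   position), `source`, `n_trials_aggregated`, `feature_shape`.
#' @export
aggregate_importance <- function(relevance,
                                 method = c("abs_mean", "mean_signed",
                                            "mean_abs")) {
  stopifnot(inherits(relevance, "relevance_map"))
  if (nrow(relevance$values) < 1) stop("empty relevance map")
  method <- match.arg(method)
  s <- switch(method,
    abs_mean = abs(colMeans(relevance$values)),
    mean_signed = colMeans(relevance$values),
    mean_abs = colMeans(abs(relevance$values)))
  importance_profile(s, "lrp", nrow(relevance$values),
                     relevance$feature_shape)
}

importance_profile <- function(scores, source, n_trials, feature_shape = NULL) {
  if (any(!is.finite(scores))) stop("importance scores must be finite")
  structure(list(scores = as.numeric(scores), source = source,
                 n_trials_aggregated = n_trials,
                 feature_shape = feature_shape),
            class = "importance_profile")
}

#' @export
print.importance_profile <- function(x, ...) {
  cat(sprintf("<importance_profile %s> %d positions from %d trials\n",
              x$source, length(x$scores), x$n_trials_aggregated))
  invisible(x)
}

#' Build a keep/mask indicator from an importance profile
#'
#' Masks exactly `floor(fraction * N)` positions with the lowest scores;
#' ties are broken by ascending position index.
#'
#' @param profile an `importance_profile` (or bare numeric score vector).
#' @param fraction fraction of positions to mask, in `[0, 1]`.
#' @return A `feature_mask`: list with logical `keep`, `fraction_masked`,
#'   `tie_policy`.
#' @export
build_mask <- function(profile, fraction = 0.1) {
  scores <- if (inherits(profile, "importance_profile")) profile$scores
            else as.numeric(profile)
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  n <- length(scores)
  m <- floor(fraction * n)
  keep <- rep(TRUE, n)
  if (m > 0) keep[order(scores, seq_len(n))[seq_len(m)]] <- FALSE
  structure(list(keep = keep, fraction_masked = fraction,
                 tie_policy = "ascending_index"),
            class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat(sprintf("<feature_mask> %d / %d positions masked (fraction %.3g)\n",
              sum(!x$keep), length(x$keep), x$fraction_masked))
  invisible(x)
}

#' Apply a feature mask
#'
#' Sets masked positions to zero in every trial; kept positions are
#' unchanged. Idempotent.
#'
#' @param features a `feature_tensor` (or trials x positions matrix).
#' @param mask a [build_mask()] result of matching length.
#' @return Object of the same type with masked positions zeroed.
#' @export
apply_mask <- function(features, mask) {
  is_ft <- inherits(features, "feature_tensor")
  v <- if (is_ft) features$values else as.matrix(features)
  if (ncol(v) != length(mask$keep))
    stop("mask length does not match the number of feature positions")
  v <- sweep(v, 2, as.numeric(mask$keep), `*`)
  if (is_ft) { features$values <- v; features } else v
}

feature_matrix_of <- function(features) {
  if (inherits(features, "feature_tensor")) features$values
  else as.matrix(features)
}

#' ANOVA-F importance
#'
#' Per-position one-way ANOVA F statistic across classes (between-group over
#' within-group mean squares); higher means more class-discriminative.
#' A position with zero within- and between-group variance scores 0
#' (0/0 := 0 convention).
#'
#' @param features a `feature_tensor` or trials x positions matrix.
#' @param labels 0-based class labels (used if `features` carries none).
#' @return An `importance_profile` with source `"anova"`.
#' @export
anova_importance <- function(features, labels = NULL) {
  x <- feature_matrix_of(features)
  y <- labels %||% features$labels
  if (is.null(y)) stop("labels required")
  y <- as.integer(y)
  cnt <- table(y)
  if (length(cnt) < 2 || any(cnt < 2))
    stop("need >= 2 classes with >= 2 trials each")
  n <- nrow(x); k <- length(cnt)
  gm <- colMeans(x)
  ssb <- numeric(ncol(x)); ssw <- numeric(ncol(x))
  for (g in names(cnt)) {
    xg <- x[y == as.integer(g), , drop = FALSE]
    mg <- colMeans(xg)
    ssb <- ssb + nrow(xg) * (mg - gm)^2
    ssw <- ssw + colSums(sweep(xg, 2, mg)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[ssb == 0] <- 0                      # constant columns: 0/0 := 0
  importance_profile(f, "anova", n,
                     if (inherits(features, "feature_tensor"))
                       features$feature_shape else NULL)
}

# mutual information between two discrete codes, natural log
discrete_mi <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  pp <- outer(pa, pb)
  sel <- p > 0
  sum(p[sel] * log(p[sel] / pp[sel]))
}

quantile_bin <- function(x, bins = 3) {
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = bins + 1))
  qs <- unique(qs)
  if (length(qs) < 2) return(rep(1L, length(x)))  # constant column
  cut(x, breaks = qs, include.lowest = TRUE, labels = FALSE)
}

#' Minimum-redundancy maximum-relevance importance
#'
#' Greedy mRMR on quantile-discretized features: relevance is the mutual
#' information (MI) with the class labels, redundancy the mean MI with the
#' already-selected set; each step picks the feature maximizing
#' relevance - redundancy. The selection order is converted into scores so
#' [build_mask()] with `fraction = 1 - n_keep/N` reproduces the kept set.
#'
#' @param features a `feature_tensor` or trials x positions matrix.
#' @param labels 0-based class labels.
#' @param n_keep number of features to select.
#' @param bins number of quantile bins for discretization.
#' @return An `importance_profile` with source `"mrmr"`.
#' @export
mrmr_importance <- function(features, labels = NULL, n_keep, bins = 3) {
  x <- feature_matrix_of(features)
  y <- labels %||% features$labels
  if (is.null(y)) stop("labels required")
  n_feat <- ncol(x)
  if (n_keep <= 0) stop("n_keep must be positive")
  n_keep <- min(n_keep, n_feat)
  xd <- apply(x, 2, quantile_bin, bins = bins)
  rel <- vapply(seq_len(n_feat), function(j) discrete_mi(xd[, j], y),
                numeric(1))
  selected <- integer(0)
  remaining <- seq_len(n_feat)
  red_sum <- numeric(n_feat)
  scores <- numeric(n_feat)
  for (step in seq_len(n_keep)) {
    crit <- if (length(selected) == 0) rel[remaining]
            else rel[remaining] - red_sum[remaining] / length(selected)
    pick <- remaining[which.max(crit)]   # first maximum: index tie-break
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    scores[pick] <- n_feat - step + 1    # earlier pick = higher score
    if (length(remaining) > 0)
      red_sum[remaining] <- red_sum[remaining] +
        vapply(remaining, function(j) discrete_mi(xd[, j], xd[, pick]),
               numeric(1))
  }
  # unselected features rank strictly below every selected one, ordered by
  # their label relevance for determinism
  if (length(remaining) > 0)
    scores[remaining] <- rank(rel[remaining], ties.method = "first") /
      (n_feat + 1)
  importance_profile(scores, "mrmr", nrow(x),
                     if (inherits(features, "feature_tensor"))
                       features$feature_shape else NULL)
}

# closed-form ridge regression onto one-hot class indicators; returns the
# coefficient matrix (features x classes) on standardized inputs
ridge_weights <- function(x, y, lambda = 1) {
  mu <- colMeans(x)
  sd <- pmax(apply(x, 2, stats::sd), 1e-12)
  xs <- sweep(sweep(x, 2, mu), 2, sd, `/`)
  yy <- outer(y, sort(unique(y)), `==`) * 1
  solve(crossprod(xs) + lambda * diag(ncol(xs)), crossprod(xs, yy))
}

#' Recursive-feature-elimination importance
#'
#' Iteratively fits an L2-regularized linear classifier (closed-form ridge
#' regression onto one-hot class indicators, standardized features), drops
#' the `step_fraction` of remaining features with the smallest aggregate
#' weight magnitude, and repeats until `n_keep` remain. The elimination round
#' is encoded as the score (survivors highest, refined by their final
#' weights).
#'
#' @param features a `feature_tensor` or trials x positions matrix.
#' @param labels 0-based class labels.
#' @param n_keep number of features to retain.
#' @param step_fraction fraction of remaining features dropped per round.
#' @param lambda ridge penalty.
#' @return An `importance_profile` with source `"rfe"`.
#' @export
rfe_importance <- function(features, labels = NULL, n_keep,
                           step_fraction = 0.1, lambda = 1) {
  x <- feature_matrix_of(features)
  y <- labels %||% features$labels
  if (is.null(y)) stop("labels required")
  n_feat <- ncol(x)
  if (n_keep <= 0 || n_keep > n_feat) stop("n_keep must be in [1, N]")
  remaining <- seq_len(n_feat)
  scores <- numeric(n_feat)
  round_i <- 0
  repeat {
    round_i <- round_i + 1
    W <- tryCatch(ridge_weights(x[, remaining, drop = FALSE], y, lambda),
                  error = function(e)
                    stop("linear classifier fit failed: ",
                         conditionMessage(e)))
    wmag <- sqrt(rowSums(W^2))
    if (length(remaining) <= n_keep) {
      scores[remaining] <- round_i + rank(wmag, ties.method = "first") /
        (n_feat + 1)
      break
    }
    n_drop <- min(max(1, floor(step_fraction * length(remaining))),
                  length(remaining) - n_keep)
    drop_idx <- order(wmag, seq_along(wmag))[seq_len(n_drop)]
    scores[remaining[drop_idx]] <- round_i +
      rank(wmag[drop_idx], ties.method = "first") / (n_feat + 1)
    remaining <- remaining[-drop_idx]
  }
  importance_profile(scores, "rfe", nrow(x),
                     if (inherits(features, "feature_tensor"))
                       features$feature_shape else NULL)
}
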