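# Epsilon-stabilized layer-wise relevance propagation (LRP).
#
# The class score f(x) (pre-softmax) is taken as the output-layer relevance
# and redistributed backwards with the epsilon rule
#
#   R_i = sum_j  z_ij / (sum_i' z_i'j + eps * sign(sum_i' z_i'j)) * R_j,
#   z_ij = x_i * w_ij,
#
# where sign(0) := +1 by declared convention. Biases receive no relevance
# (z excludes b), so with eps = 0 and bias-free layers the layer sums are
# exactly conserved: sum_i R_i = f(x). The default pipeline propagates only
# through the dense classifier C, landing on the extracted feature map;
# generic conv / average-pooling rules are provided for deeper propagation.

signp <- function(x) ifelse(x >= 0, 1, -1)  # sign with sign(0) := +1

#' LRP configuration
#'
#' @param epsilon stabilizer added to the denominator (times the sign of the
#'   pre-activation sum); must be >= 0. The default 1e-6 keeps the
#'   conservation deviation negligible on unit-scale features.
#' @param target_rule `"true_label"` (relevance of the correct class;
#'   used when scoring training trials) or `"predicted_label"`.
#' @return An `lrp_config` list.
#' @export
lrp_config <- function(epsilon = 1e-6,
                       target_rule = c("true_label", "predicted_label")) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  structure(list(epsilon = epsilon, target_rule = match.arg(target_rule)),
            class = "lrp_config")
}

#' Output-layer relevance initialization
#'
#' The starting relevance vector: the pre-softmax class score f(x) at the
#' target class, zero elsewhere (so its sum equals f(x)).
#'
#' @param class_scores numeric vector of pre-softmax scores for one trial.
#' @param target_class 0-based target class index.
#' @return Numeric vector of the same length.
#' @export
init_relevance <- function(class_scores, target_class) {
  k <- length(class_scores)
  if (target_class < 0 || target_class >= k) stop("target_class out of range")
  r <- numeric(k)
  r[target_class + 1L] <- class_scores[target_class + 1L]
  r
}

#' Epsilon-rule relevance redistribution through a dense layer
#'
#' Redistributes upper-layer relevance onto the layer inputs proportionally
#' to the contributions `z_ij = x_i w_ij`, with the epsilon-stabilized
#' denominator. Bias terms absorb no relevance.
#'
#' @param x input vector of the dense layer (length I).
#' @param w weight matrix, I x J (inputs in rows, units in columns).
#' @param upper_relevance relevance vector of the J upper units.
#' @param epsilon stabilizer >= 0; with `epsilon = 0` a zero pre-activation
#'   column sum carrying nonzero relevance is an error.
#' @return Lower-layer relevance vector of length I.
#' @export
relevance_dense <- function(x, w, upper_relevance, epsilon = 1e-6) {
  w <- as.matrix(w)
  if (length(x) != nrow(w) || length(upper_relevance) != ncol(w))
    stop("inconsistent shapes in relevance_dense")
  z_sum <- as.numeric(crossprod(w, x))  # sum_i x_i w_ij per unit j
  if (epsilon == 0 && any(z_sum == 0 & upper_relevance != 0))
    stop("zero pre-activation sum with nonzero relevance; set epsilon > 0")
  denom <- z_sum + epsilon * signp(z_sum)
  s <- ifelse(upper_relevance == 0, 0, upper_relevance / denom)
  x * as.numeric(w %*% s)
}

# epsilon rule through a convolution layer (weights only, bias absorbed):
# z-sums via the forward conv without bias, redistribution via the adjoint.
relevance_conv <- function(x4d, layer, upper_relevance4d, epsilon = 1e-6) {
  z <- conv2d_fwd(x4d, layer$W, numeric(0),
                  layer$pad_h, layer$pad_w, layer$groups)
  if (epsilon == 0 && any(z == 0 & upper_relevance4d != 0))
    stop("zero pre-activation sum with nonzero relevance; set epsilon > 0")
  s <- upper_relevance4d / (z + epsilon * signp(z))
  s[upper_relevance4d == 0] <- 0
  dim(s) <- dim(z)
  cx <- conv2d_bwd(x4d, layer$W, s, layer$pad_h, layer$pad_w,
                   layer$groups, TRUE)$gx
  r <- x4d * cx
  dim(r) <- dim(x4d)
  r
}

# proportional redistribution through average pooling: each input position
# receives x_i / (window sum + eps sign) of the window's relevance
relevance_avgpool <- function(x4d, layer, upper_relevance4d, epsilon = 1e-6) {
  k <- layer$kh * layer$kw
  win_sum <- pool2d_fwd(x4d, layer$kh, layer$kw, layer$sh, layer$sw, FALSE)$y * k
  s <- upper_relevance4d / (win_sum + epsilon * signp(win_sum))
  s[upper_relevance4d == 0] <- 0
  dim(s) <- dim(win_sum)
  spread <- pool2d_bwd(s, as.integer(dim(x4d)), layer$kh, layer$kw,
                       layer$sh, layer$sw, FALSE, integer(0)) * k
  r <- x4d * spread
  dim(r) <- dim(x4d)
  r
}

#' Propagate class-score relevance onto the feature map
#'
#' Per trial: initialize the output relevance at the target class's
#' pre-softmax score, then redistribute through the dense classifier C with
#' the epsilon rule, yielding a signed relevance value for every feature-map
#' position.
#'
#' @param model a trained `backbone_model`.
#' @param features a `feature_tensor` from [extract_features()].
#' @param cfg an [lrp_config()]; `target_rule = "true_label"` requires the
#'   feature tensor to carry labels.
#' @return A `relevance_map`: list with `values` (trials x positions),
#'   `target_class` per trial, `feature_shape` and `config`.
#' @export
propagate_to_feature_map <- function(model, features, cfg = lrp_config()) {
  stopifnot(inherits(model, "backbone_model"),
            inherits(features, "feature_tensor"))
  pred <- predict_backbone(model, features)
  target <- switch(cfg$target_rule,
    true_label = {
      if (is.null(features$labels)) stop("true_label rule needs labels")
      features$labels
    },
    predicted_label = pred$labels)
  n <- nrow(features$values)
  rel <- matrix(0, n, model$n_feat)
  for (i in seq_len(n)) {
    r0 <- init_relevance(pred$scores[i, ], target[i])
    rel[i, ] <- relevance_dense(features$values[i, ], model$W, r0,
                                cfg$epsilon)
  }
  if (any(!is.finite(rel)))
    stop("non-finite relevance propagated through classifier C")
  structure(list(values = rel, target_class = target,
                 feature_shape = features$feature_shape, config = cfg),
            class = "relevance_map")
}

#' Audit the conservation property across layers
#'
#' Reports, for each layer's relevance vector, its sum and the absolute
#' deviation from the output score f(x). With `eps = 0`, no biases and no
#' zero pre-activation sums the deviations are zero up to round-off; with
#' eps > 0 they grow with eps and are reported, not asserted.
#'
#' @param relevances list of per-layer relevance vectors/arrays (output layer
#'   first or last, any order).
#' @param f_x the output score the decomposition should conserve.
#' @return list with per-layer `sums`, `deviations`, and `max_deviation`.
#' @export
conservation_audit <- function(relevances, f_x) {
  if (length(relevances) < 2)
    stop("need at least two layers of relevance to audit")
  sums <- vapply(relevances, function(r) sum(r), numeric(1))
  dev <- abs(sums - f_x)
  list(sums = sums, deviations = dev, max_deviation = max(dev))
}

#' Export a relevance heatmap
#'
#' Aggregates a relevance map to a 2-D array (feature-map channels x time
#' positions), writes the raw array (RDS, bit-exact, plus CSV) and renders a
#' PNG heatmap.
#'
#' @param relevance a `relevance_map`.
#' @param aggregate `"mean_over_trials"` (signed mean) or `"per_trial"`.
#' @param file_prefix output path prefix (`.rds`, `.csv`, `.png` appended).
#' @param trial trial index when `aggregate = "per_trial"`.
#' @return The aggregated 2-D array, invisibly.
#' @export
heatmap_export <- function(relevance, aggregate = c("mean_over_trials",
                                                    "per_trial"),
                           file_prefix, trial = 1) {
  stopifnot(inherits(relevance, "relevance_map"))
  if (nrow(relevance$values) == 0) stop("empty relevance map")
  aggregate <- match.arg(aggregate)
  v <- switch(aggregate,
    mean_over_trials = colMeans(relevance$values),
    per_trial = relevance$values[trial, ])
  fs <- relevance$feature_shape  # (channels, height, width)
  a <- array(v, dim = fs)
  m <- matrix(aperm(a, c(1, 3, 2)), nrow = fs[1])  # channels x (time * height)
  dir.create(dirname(file_prefix), recursive = TRUE, showWarnings = FALSE)
  saveRDS(m, paste0(file_prefix, ".rds"))
  utils::write.table(m, paste0(file_prefix, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  grDevices::png(paste0(file_prefix, ".png"), width = 640, height = 480)
  graphics::image(t(m), xlab = "feature-map time", ylab = "feature-map channel",
                  main = paste("LRP relevance,", aggregate),
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE))
  grDevices::dev.off()
  invisible(m)
}
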