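# Importance aggregation, mask construction/application, and the baseline
# selectors (ANOVA F, mRMR, RFE).

test_that("aggregate_importance reduces trials as specified", {
  v <- matrix(c(1, -2, 3, -1, 2, -3), 2, 3, byrow = TRUE)
  rel <- structure(list(values = v, target_class = c(0L, 1L),
                        feature_shape = c(3L, 1L, 1L),
                        config = lrp_config()),
                   class = "relevance_map")
  expect_equal(aggregate_importance(rel, "mean_signed")$scores, c(0, 0, 0))
  expect_equal(aggregate_importance(rel, "mean_abs")$scores, c(1, 2, 3))
  expect_equal(aggregate_importance(rel, "abs_mean")$scores, c(0, 0, 0))
  one <- rel; one$values <- v[1, , drop = FALSE]
  expect_equal(aggregate_importance(one, "mean_signed")$scores, v[1, ])
  expect_equal(aggregate_importance(one)$scores, abs(v[1, ]))
  # permutation equivariance
  perm <- c(3, 1, 2)
  relp <- rel; relp$values <- v[, perm]
  expect_equal(aggregate_importance(relp, "mean_abs")$scores,
               aggregate_importance(rel, "mean_abs")$scores[perm])
})

test_that("build_mask masks exactly floor(fraction * N) lowest scores", {
  set.seed(8)
  for (n in c(10, 100, 257)) for (fr in c(0, 0.1, 0.5, 1)) {
    s <- rnorm(n)
    mk <- build_mask(s, fr)
    expect_equal(sum(!mk$keep), floor(fr * n))
    if (any(!mk$keep) && any(mk$keep))
      expect_lte(max(s[!mk$keep]), min(s[mk$keep]))
  }
  # declared tie policy: ascending position index
  mk <- build_mask(rep(0, 10), 0.5)
  expect_equal(which(!mk$keep), 1:5)
})

test_that("apply_mask zeroes masked positions and is idempotent", {
  x <- matrix(1:12, 3, 4)
  mk <- build_mask(c(4, 1, 3, 2), 0.5)   # masks positions 2 and 4
  out <- apply_mask(x, mk)
  expect_equal(out[, c(2, 4)], matrix(0, 3, 2))
  expect_equal(out[, c(1, 3)], x[, c(1, 3)])
  expect_equal(apply_mask(out, mk), out)
  expect_equal(apply_mask(x, build_mask(1:4, 0)), x)
  expect_equal(apply_mask(x, build_mask(1:4, 1)), matrix(0, 3, 4))
  expect_error(apply_mask(x, build_mask(1:5, 0.2)), "match")
})

test_that("ANOVA F agrees with stats::aov and the t^2 identity", {
  set.seed(14)
  x <- matrix(rnorm(60 * 8), 60)
  y <- rep(0:2, each = 20)
  x[, 3] <- x[, 3] + y
  prof <- anova_importance(x, y)
  for (j in c(1, 3, 7)) {
    f_ref <- summary(stats::aov(x[, j] ~ factor(y)))[[1]]$`F value`[1]
    expect_equal(prof$scores[j], f_ref, tolerance = 1e-10)
  }
  # two classes: F equals the squared pooled-variance t statistic
  y2 <- rep(0:1, each = 30)
  prof2 <- anova_importance(x, y2)
  tt <- stats::t.test(x[, 5] ~ y2, var.equal = TRUE)$statistic
  expect_equal(prof2$scores[5], unname(tt^2), tolerance = 1e-10)
  # constant feature: 0/0 := 0
  xc <- x; xc[, 2] <- 1
  expect_equal(anova_importance(xc, y)$scores[2], 0)
  expect_error(anova_importance(x[1:3, ], rep(0:2, 1)), ">= 2")
})

test_that("mRMR prefers relevance and penalizes redundancy", {
  set.seed(6)
  n <- 400
  y <- rep(0:1, each = n / 2)
  base <- rnorm(n) + 2 * y
  x <- cbind(base,                       # informative
             base + rnorm(n, sd = 0.05), # near-duplicate of column 1
             rnorm(n) + 1.5 * y,         # informative, independent
             rnorm(n), rnorm(n), rnorm(n))
  prof <- mrmr_importance(x, y, n_keep = 3)
  picks <- order(prof$scores, decreasing = TRUE)[1:3]
  # first pick is the feature with maximal label MI
  mi <- vapply(1:6, function(j)
    lrpselect:::discrete_mi(lrpselect:::quantile_bin(x[, j]), y), numeric(1))
  expect_equal(picks[1], which.max(mi))
  # the duplicated pair contributes only one of its two members
  expect_lt(sum(picks %in% c(1, 2)), 2)
  expect_true(3 %in% picks)
  # independent labels: selection order is seed-stable (deterministic re-run)
  y_ind <- sample(0:1, n, TRUE)
  p1 <- mrmr_importance(x, y_ind, n_keep = 4)
  p2 <- mrmr_importance(x, y_ind, n_keep = 4)
  expect_identical(p1$scores, p2$scores)
  expect_error(mrmr_importance(x, y, n_keep = 0), "positive")
})

test_that("RFE keeps strong features and honours one-step reduction", {
  tb <- generate_feature_table(
    planted_feature_spec(30, c(4, 17), class_mean_shift = 4, noise_sd = 0.5,
                         n_samples_per_class = 80, seed = 3))
  prof <- rfe_importance(tb$x, tb$y, n_keep = 2, step_fraction = 0.2)
  expect_setequal(order(prof$scores, decreasing = TRUE)[1:2], c(4, 17))
  # one-step elimination equals ranking by the first fit's weights
  prof1 <- rfe_importance(tb$x, tb$y, n_keep = 2, step_fraction = 1)
  W <- lrpselect:::ridge_weights(tb$x, tb$y, 1)
  first_rank <- order(sqrt(rowSums(W^2)), decreasing = TRUE)[1:2]
  expect_setequal(order(prof1$scores, decreasing = TRUE)[1:2], first_rank)
  expect_identical(prof$scores,
                   rfe_importance(tb$x, tb$y, n_keep = 2,
                                  step_fraction = 0.2)$scores)
})

test_that("selector profiles reproduce their kept set through build_mask", {
  tb <- generate_feature_table(
    planted_feature_spec(40, 1:8, class_mean_shift = 3,
                         n_samples_per_class = 50, seed = 5))
  n_keep <- 36                          # mask fraction 0.1
  for (prof in list(mrmr_importance(tb$x, tb$y, n_keep = n_keep),
                    rfe_importance(tb$x, tb$y, n_keep = n_keep))) {
    mk <- build_mask(prof, 0.1)
    expect_equal(sum(mk$keep), n_keep)
  }
})

test_that("planted informative features are retrieved by every selector", {
  # strong effects, k/N = 0.1: the top-k set equals the planted set
  tb <- generate_feature_table(
    planted_feature_spec(50, seq(3, 48, by = 9), class_mean_shift = 4,
                         noise_sd = 1, n_samples_per_class = 60, seed = 10))
  k <- length(tb$informative)
  for (prof in list(anova_importance(tb$x, tb$y),
                    mrmr_importance(tb$x, tb$y, n_keep = k),
                    rfe_importance(tb$x, tb$y, n_keep = k))) {
    topk <- order(prof$scores, decreasing = TRUE)[seq_len(k)]
    expect_setequal(topk, tb$informative)
  }
})
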