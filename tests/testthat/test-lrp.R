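# Epsilon-rule relevance redistribution: definitional cases, conservation,
# the closed-form one-layer oracle, and the generic conv/pool rules.

test_that("init_relevance puts f(x) at the target and zero elsewhere", {
  expect_equal(init_relevance(c(1.2, -0.3), 0), c(1.2, 0))
  expect_equal(init_relevance(c(0, 0), 1), c(0, 0))
  s <- c(0.4, -1.1, 2.2)
  expect_equal(sum(init_relevance(s, 2)), s[3])
  expect_error(init_relevance(s, 3), "out of range")
})

test_that("relevance_dense matches hand-computed redistribution", {
  # proportional split: z = (2, 3), column sum 5, R = 5
  expect_equal(relevance_dense(c(2, 3), matrix(c(1, 1), 2, 1), 5, 0),
               c(2, 3))
  # single path passes all relevance
  expect_equal(relevance_dense(4, matrix(0.5), 2, 0), 2)
  # zero column sum with eps = 0 is rejected
  expect_error(relevance_dense(c(1, -1), matrix(c(1, 1), 2, 1), 1, 0),
               "epsilon")
  # zero column sum, eps = 0.01, sign(0) := +1: denominator is +0.01
  x <- c(1, -1, 2); w <- matrix(c(1, 2, 0.5), 3, 1)
  z <- x * w[, 1]                        # sums to 0
  expect_equal(sum(z), 0)
  expect_equal(relevance_dense(x, w, 1, 0.01), z / 0.01)
})

test_that("conservation holds exactly for eps = 0 bias-free layers", {
  set.seed(7)
  for (rep in 1:100) {
    n_in <- sample(3:12, 1); n_out <- sample(2:6, 1)
    x <- rnorm(n_in); w <- matrix(rnorm(n_in * n_out), n_in, n_out)
    R_up <- rnorm(n_out)
    if (any(abs(crossprod(w, x)) < 1e-6)) next
    R_lo <- relevance_dense(x, w, R_up, 0)
    expect_equal(sum(R_lo), sum(R_up), tolerance = 1e-10)
  }
})

test_that("conservation deviation grows monotonically with epsilon", {
  set.seed(3)
  x <- abs(rnorm(8)) + 0.5
  w <- matrix(abs(rnorm(8 * 3)) + 0.1, 8, 3)  # positive z-sums
  R_up <- c(2, 1, 0.5)
  devs <- vapply(c(0, 0.01, 0.1, 1), function(eps)
    abs(sum(relevance_dense(x, w, R_up, eps)) - sum(R_up)), numeric(1))
  expect_equal(devs[1], 0, tolerance = 1e-12)
  expect_true(all(diff(devs) > 0))
})

test_that("one-layer oracle: relevance equals the x*w decomposition", {
  # closed form: with a single output unit, R_i = x_i w_i / sum(x w) * f,
  # i.e. the x_i * w_i contributions rescaled to sum to f(x)
  set.seed(12)
  for (rep in 1:50) {
    n <- sample(4:20, 1)
    x <- rnorm(n); w <- rnorm(n)
    f <- sum(x * w)
    if (abs(f) < 1e-3) next
    got <- relevance_dense(x, matrix(w), f, 0)
    expect_equal(got, x * w, tolerance = 1e-10)
  }
})

test_that("propagate_to_feature_map conserves, concentrates and scales", {
  set.seed(21)
  n_feat <- 30; n_cls <- 4; n_tr <- 12
  m <- dense_classifier(n_feat, n_cls)
  m$W <- matrix(rnorm(n_feat * n_cls), n_feat, n_cls)
  m$b <- numeric(n_cls)                  # bias-free: exact conservation
  ft <- as_feature_tensor(matrix(rnorm(n_tr * n_feat), n_tr),
                          labels = sample(0:(n_cls - 1), n_tr, TRUE))
  rel <- propagate_to_feature_map(m, ft, lrp_config(epsilon = 0))
  sc <- predict_backbone(m, ft)$scores
  f_tgt <- sc[cbind(seq_len(n_tr), ft$labels + 1L)]
  expect_equal(rowSums(rel$values), f_tgt, tolerance = 1e-8)
  # a single nonzero feature receives all the relevance
  one <- as_feature_tensor(matrix(c(rep(0, 4), 2, rep(0, n_feat - 5)), 1),
                           labels = 1L)
  rel1 <- propagate_to_feature_map(m, one, lrp_config(epsilon = 0))
  expect_equal(which(rel1$values[1, ] != 0), 5L)
  # doubling C's weights doubles f(x) and total relevance
  m2 <- m; m2$W <- 2 * m$W
  rel2 <- propagate_to_feature_map(m2, ft, lrp_config(epsilon = 0))
  expect_equal(rowSums(rel2$values), 2 * f_tgt, tolerance = 1e-8)
  # scale covariance in the features
  ft3 <- ft; ft3$values <- 3 * ft$values
  rel3 <- propagate_to_feature_map(m, ft3, lrp_config(epsilon = 0))
  expect_equal(rowSums(rel3$values), 3 * f_tgt, tolerance = 1e-8)
})

test_that("conservation_audit reports layer sums against f(x)", {
  a <- conservation_audit(list(c(1, 2), c(1.5, 1.5), 3), 3)
  expect_equal(a$max_deviation, 0)
  expect_equal(conservation_audit(list(0, c(0, 0)), 0)$max_deviation, 0)
  expect_error(conservation_audit(list(1), 1), "two layers")
})

test_that("generic conv and avg-pool rules conserve relevance", {
  set.seed(9)
  x <- array(rnorm(1 * 2 * 3 * 8), c(1, 2, 3, 8))
  cl <- lrpselect:::nn_conv(2, 3, 2, 3, pad_h = 0, pad_w = 1)
  z <- lrpselect:::conv2d_fwd(x, cl$W, numeric(0), cl$pad_h, cl$pad_w, 1L)
  R_up <- array(rnorm(length(z)), dim(z))
  R_lo <- lrpselect:::relevance_conv(x, cl, R_up, 0)
  expect_equal(sum(R_lo), sum(R_up), tolerance = 1e-8)
  pl <- lrpselect:::nn_pool("avg", 1, 2)
  zp <- lrpselect:::pool2d_fwd(x, 1L, 2L, 1L, 2L, FALSE)$y
  Rp <- array(abs(rnorm(length(zp))) + 0.1, dim(zp))
  R_lo_p <- lrpselect:::relevance_avgpool(x, pl, Rp, 1e-9)
  expect_equal(sum(R_lo_p), sum(Rp), tolerance = 1e-6)
})

test_that("heatmap export writes bit-exact arrays", {
  set.seed(5)
  m <- dense_classifier(12, 2)
  ft <- as_feature_tensor(matrix(rnorm(24), 2), labels = c(0L, 1L))
  rel <- propagate_to_feature_map(m, ft)
  td <- withr::local_tempdir()
  a <- heatmap_export(rel, "mean_over_trials", file.path(td, "hm"))
  expect_identical(readRDS(file.path(td, "hm.rds")), a)
  expect_true(file.exists(file.path(td, "hm.png")))
  expect_equal(as.numeric(a), colMeans(rel$values))
  # symmetric trials cancel under the signed mean
  rel$values[2, ] <- -rel$values[1, ]
  a2 <- heatmap_export(rel, "mean_over_trials", file.path(td, "hm2"))
  expect_equal(max(abs(a2)), 0)
  a3 <- heatmap_export(rel, "per_trial", file.path(td, "hm3"), trial = 1)
  expect_equal(as.numeric(a3), rel$values[1, ])
})
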