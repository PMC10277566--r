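# Backbone construction, the extractor/classifier boundary, training
# determinism, and masked prediction.

test_that("backbone architectures follow their stated conventions", {
  m <- build_backbone("eegnet", 22, 1125, 4, 250)
  # temporal kernel = half the sampling rate, spatial kernel spans channels
  expect_equal(dim(m$layers[[1]]$W)[4], 125)
  expect_equal(dim(m$layers[[3]]$W)[3], 22)
  expect_equal(ncol(m$W), 4)           # classifier output dimension
  expect_equal(m$n_feat, prod(m$feature_shape))
  # DeepConvNet: four convolution blocks with max pooling
  md <- build_backbone("deepconvnet", 8, 600, 2, 250)
  expect_equal(sum(vapply(md$layers, function(l)
    l$type == "pool" && l$mode == "max", logical(1))), 4)
  # ShallowConvNet: square / log with average pooling
  ms <- build_backbone("shallowconvnet", 8, 600, 2, 250)
  expect_equal(sum(vapply(ms$layers, function(l)
    l$type == "pool" && l$mode == "avg", logical(1))), 1)
  expect_true(any(vapply(ms$layers, function(l)
    l$type == "act" && l$fun == "square", logical(1))))
  expect_error(build_backbone("lstm", 8, 600, 2, 250), "unknown backbone")
})

test_that("feature extraction is deterministic, finite and shape-stable", {
  m <- build_backbone("eegnet", 4, 250, 2, 125)
  ep <- epoch_set(array(0, c(3, 4, 250)), c(0L, 1L, 0L), 125, c(0, 2))
  ft <- extract_features(m, ep)
  expect_true(all(is.finite(ft$values)))
  expect_equal(ncol(ft$values), prod(m$feature_shape))
  # identical trials give identical feature vectors
  set.seed(1)
  trial <- array(rnorm(4 * 250), c(1, 4, 250))
  dat <- array(0, c(2, 4, 250))
  dat[1, , ] <- trial; dat[2, , ] <- trial
  ft2 <- extract_features(m, epoch_set(dat, c(0L, 1L), 125, c(0, 2)))
  expect_identical(ft2$values[1, ], ft2$values[2, ])
  expect_error(extract_features(m, epoch_set(array(0, c(2, 5, 250)),
                                             c(0L, 1L), 125, c(0, 2))),
               "does not match")
})

test_that("masked prediction degenerates correctly at the extremes", {
  set.seed(3)
  m <- dense_classifier(20, 3)
  m$W <- matrix(rnorm(60), 20, 3)
  m$b <- c(0.3, -0.2, 0.1)
  ft <- as_feature_tensor(matrix(rnorm(100), 5))
  p0 <- predict_backbone(m, ft)
  expect_equal(dim(p0$scores), c(5, 3))
  # fraction-0 mask: predictions bitwise equal to unmasked
  pm <- predict_backbone(m, ft, build_mask(rnorm(20), 0))
  expect_identical(p0$scores, pm$scores)
  # full mask: scores equal the bias for every trial
  pf <- predict_backbone(m, ft, build_mask(rnorm(20), 1))
  expect_equal(pf$scores, matrix(m$b, 5, 3, byrow = TRUE))
})

test_that("training is seed-reproducible and rejects degenerate inputs", {
  sess <- small_sessions(n_channels = 4, n_trials_per_class = 8, seed = 6)
  cfg <- train_config(epochs = 2, batch_size = 8, seed = 42)
  d <- dim(sess$train$data)
  m0 <- build_backbone("eegnet", d[2], d[3], 2, sess$train$sfreq)
  m1 <- train_backbone(m0, sess$train, cfg)
  m2 <- train_backbone(m0, sess$train, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$W, m2$W)
  expect_identical(lapply(m1$layers, `[[`, "W"),
                   lapply(m2$layers, `[[`, "W"))
  # a missing class is rejected
  bad <- sess$train
  bad$labels[] <- 0L
  expect_error(train_backbone(m0, bad, cfg), "every class")
  bad2 <- sess$train
  bad2$labels[1] <- 5L
  expect_error(train_backbone(m0, bad2, cfg), "n_classes")
})

test_that("extractor plus classifier equals the full forward pass", {
  sess <- small_sessions(n_channels = 4, n_trials_per_class = 6, seed = 2)
  d <- dim(sess$train$data)
  m <- build_backbone("shallowconvnet", d[2], d[3], 2, sess$train$sfreq)
  m <- train_backbone(m, sess$train, train_config(epochs = 1, batch_size = 6,
                                                  seed = 1))
  ft <- extract_features(m, sess$test)
  p <- predict_backbone(m, ft)
  manual <- ft$values %*% m$W + rep(m$b, each = nrow(ft$values))
  expect_identical(p$scores, manual)
})

test_that("shuffled labels train to chance-level test accuracy", {
  sess <- small_sessions(n_channels = 4, n_trials_per_class = 20, seed = 9)
  tr <- sess$train
  tr$labels <- lrpselect:::with_seed(99, sample(tr$labels))
  d <- dim(tr$data)
  m <- build_backbone("eegnet", d[2], d[3], 2, tr$sfreq)
  m <- train_backbone(m, tr, train_config(epochs = 10, batch_size = 20,
                                          seed = 1))
  acc <- accuracy(predict_backbone(m, extract_features(m, sess$test))$labels,
                  sess$test$labels)
  # chance is 50%; binomial error over 40 test trials
  expect_lt(abs(acc - 50), 3 * 100 * sqrt(0.25 / 40))
})
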