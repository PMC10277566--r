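# Shared fixtures, built in code. Sizes are kept small so the whole suite
# runs quickly on one CPU; the synthetic generator defaults (250 Hz, 4-s
# imagery) are exercised where the property under test needs them.

# a small two-class ERD recording pair (train/test "sessions")
small_sessions <- function(n_channels = 8, n_trials_per_class = 30,
                           n_classes = 2, erd_depth = 0.5, seed = 3,
                           target_sfreq = 125) {
  sp <- synthetic_spec(n_channels = n_channels, sfreq = 250,
                       n_trials_per_class = n_trials_per_class,
                       n_classes = n_classes, erd_depth = erd_depth,
                       seed = seed)
  sp_te <- sp
  sp_te$seed <- seed + 10000
  list(train = preprocess_recording(generate_recording(sp),
                                    target_sfreq = target_sfreq,
                                    session = "train"),
       test = preprocess_recording(generate_recording(sp_te),
                                   target_sfreq = target_sfreq,
                                   session = "test"))
}

# rank-based AUC of `positive` indices under score vector s
rank_auc <- function(s, positive) {
  r <- rank(s)
  np <- length(positive)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * (length(s) - np))
}

# brute-force two-sided Wilcoxon signed-rank p-value by enumerating all
# 2^n sign assignments (midranks for ties, zeros assumed already dropped)
wilcoxon_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.numeric(signs %*% r)
  mean(abs(Vs - mu) >= abs(V - mu) - 1e-12)
}
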