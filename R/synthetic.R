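# Synthetic motor-imagery EEG with planted event-related desynchronization
# (ERD), plus planted-effect feature tables for selector oracle tests.
#
# The generator emulates the structure of cue-based MI recordings: continuous
# 1/f background noise with a small shared-across-channels component, ongoing
# band-limited mu (8-13 Hz) and beta (13-30 Hz) rhythms on every channel, and
# cue-locked trials during which the rhythm amplitude on the labeled class's
# informative channels is attenuated by a factor (1 - erd_depth) with 0.25-s
# cosine ramps at the window edges.

# evaluate `code` under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic motor-imagery recording
#'
#' Defaults mirror a typical 22-electrode, 250 Hz cue-based MI session with
#' 4-s imagery periods and balanced classes (72 trials per class, the per-class
#' count of a 288-trial four-class session).
#'
#' @param n_channels number of electrodes.
#' @param sfreq sampling rate in Hz.
#' @param n_trials_per_class trials per class.
#' @param n_classes number of MI classes (2 or 4).
#' @param trial_duration imagery duration in seconds.
#' @param inter_trial_interval rest between trials in seconds.
#' @param mu_band,beta_band rhythm bands in Hz, `(low, high)`.
#' @param erd_depth fractional amplitude attenuation in `[0, 1]`: during a
#'   trial, rhythms on that class's informative channels are multiplied by
#'   `1 - erd_depth`.
#' @param informative_channels list of integer channel indices (1-based), one
#'   vector per class; `NULL` assigns two disjoint channels per class.
#' @param noise_scale standard-deviation scale of the 1/f background noise
#'   (the ongoing rhythms have fixed unit-scale amplitude).
#' @param seed integer RNG seed; fixed seed gives bit-identical recordings.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_channels = 22, sfreq = 250,
                           n_trials_per_class = 72, n_classes = 4,
                           trial_duration = 4, inter_trial_interval = 2,
                           mu_band = c(8, 13), beta_band = c(13, 30),
                           erd_depth = 0.5, informative_channels = NULL,
                           noise_scale = 1, seed = 1) {
  if (!n_classes %in% c(2, 4)) stop("n_classes must be 2 or 4")
  if (erd_depth < 0 || erd_depth > 1) stop("erd_depth must be in [0, 1]")
  check_band <- function(b, name) {
    if (b[1] >= b[2]) stop(name, ": low edge must be below high edge")
    if (b[2] >= sfreq / 2) stop(name, ": high edge must be below Nyquist (",
                                sfreq / 2, " Hz)")
  }
  check_band(mu_band, "mu_band"); check_band(beta_band, "beta_band")
  if (is.null(informative_channels)) {
    if (2 * n_classes > n_channels)
      stop("not enough channels for default informative channel groups")
    informative_channels <- lapply(seq_len(n_classes),
                                   function(k) c(2 * k - 1, 2 * k))
  }
  if (length(informative_channels) != n_classes)
    stop("informative_channels needs one vector per class")
  if (any(unlist(informative_channels) > n_channels))
    stop("informative channel index beyond n_channels")
  structure(list(n_channels = n_channels, sfreq = sfreq,
                 n_trials_per_class = n_trials_per_class,
                 n_classes = n_classes, trial_duration = trial_duration,
                 inter_trial_interval = inter_trial_interval,
                 mu_band = mu_band, beta_band = beta_band,
                 erd_depth = erd_depth,
                 informative_channels = informative_channels,
                 noise_scale = noise_scale, seed = seed),
            class = "synthetic_spec")
}

# column-wise coloured noise: white noise spectrally shaped by `shape(f)`,
# each column normalized to unit standard deviation
shaped_noise <- function(n_samples, n_series, sfreq, shape) {
  w <- matrix(stats::rnorm(n_samples * n_series), n_samples, n_series)
  f <- seq(0, n_samples - 1) * sfreq / n_samples
  f <- pmin(f, sfreq - f)  # two-sided frequency axis
  g <- shape(f)
  z <- stats::mvfft(w) * g
  out <- Re(stats::mvfft(z, inverse = TRUE)) / n_samples
  sweep(out, 2, pmax(apply(out, 2, stats::sd), 1e-12), `/`)
}

pink_noise <- function(n_samples, n_series, sfreq) {
  shaped_noise(n_samples, n_series, sfreq,
               function(f) 1 / sqrt(pmax(f, 1)))
}

band_noise <- function(n_samples, n_series, sfreq, band) {
  shaped_noise(n_samples, n_series, sfreq,
               function(f) as.numeric(f >= band[1] & f <= band[2]))
}

#' Generate a synthetic motor-imagery recording
#'
#' Builds a continuous multichannel signal with cue events per
#' [synthetic_spec()]: 1/f background (independent per channel plus a small
#' shared component), ongoing band-limited mu and beta rhythms, and
#' class-dependent multiplicative ERD on the informative channels during each
#' imagery window. Class order is randomized but exactly balanced.
#'
#' @param spec a [synthetic_spec()].
#' @return A [raw_recording()] whose `meta` field keeps the generating spec.
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    sf <- spec$sfreq
    n_tr <- spec$n_classes * spec$n_trials_per_class
    lead <- 2                     # seconds before the first cue
    step <- spec$trial_duration + spec$inter_trial_interval
    total_s <- lead + n_tr * step + 2
    S <- round(total_s * sf)
    Cn <- spec$n_channels

    labels <- sample(rep(seq_len(spec$n_classes) - 1L, spec$n_trials_per_class))
    onsets <- round((lead + (seq_len(n_tr) - 1) * step) * sf)  # 0-based

    bg <- pink_noise(S, Cn, sf) * spec$noise_scale
    shared <- pink_noise(S, 1, sf)[, 1] * 0.3 * spec$noise_scale
    mu <- band_noise(S, Cn, sf, spec$mu_band) * 1.0
    beta <- band_noise(S, Cn, sf, spec$beta_band) * 0.6

    # per-channel amplitude envelope: 1 outside imagery, 1 - erd_depth inside
    # the labeled class's informative channels, with 0.25-s cosine ramps
    env <- matrix(1, S, Cn)
    ns_tr <- round(spec$trial_duration * sf)
    nr <- round(0.25 * sf)
    ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))     # 0 -> 1
    win <- c(ramp, rep(1, ns_tr - 2 * nr), rev(ramp))  # attenuation weight
    for (t in seq_len(n_tr)) {
      chs <- spec$informative_channels[[labels[t] + 1L]]
      rows <- onsets[t] + seq_len(ns_tr)  # 1-based rows for 0-based onset
      env[rows, chs] <- env[rows, chs] * (1 - spec$erd_depth * win)
    }

    sig <- t(bg + shared + env * (mu + beta))
    rec <- raw_recording(sig, sf,
                         events = data.frame(sample = as.integer(onsets),
                                             label = as.integer(labels)))
    rec$meta <- spec
    rec
  })
}

#' Specification of a planted-effect feature table
#'
#' @param n_features number of feature columns.
#' @param informative_indices 1-based indices of class-informative columns.
#' @param class_mean_shift mean shift applied to an informative column in its
#'   assigned class (columns are assigned to classes round-robin).
#' @param noise_sd standard deviation of the Gaussian noise in every column.
#' @param n_samples_per_class samples per class (>= 2).
#' @param n_classes number of classes.
#' @param seed integer RNG seed.
#' @return A `planted_feature_spec` list.
#' @export
planted_feature_spec <- function(n_features, informative_indices,
                                 class_mean_shift = 2, noise_sd = 1,
                                 n_samples_per_class = 50, n_classes = 2,
                                 seed = 1) {
  if (n_samples_per_class < 2) stop("n_samples_per_class must be >= 2")
  if (any(informative_indices < 1 | informative_indices > n_features))
    stop("informative_indices out of range")
  structure(list(n_features = n_features,
                 informative_indices = as.integer(informative_indices),
                 class_mean_shift = class_mean_shift, noise_sd = noise_sd,
                 n_samples_per_class = n_samples_per_class,
                 n_classes = as.integer(n_classes), seed = seed),
            class = "planted_feature_spec")
}

#' Generate a feature table with planted class-informative columns
#'
#' Gaussian noise everywhere; each informative column additionally receives a
#' `class_mean_shift` offset in one class (assigned round-robin across the
#' informative columns), so its one-way effect size is `shift / noise_sd`.
#'
#' @param spec a [planted_feature_spec()].
#' @return list with `x` (samples x features matrix), `y` (0-based labels) and
#'   `informative` (1-based informative column indices).
#' @export
generate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "planted_feature_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples_per_class * spec$n_classes
    y <- rep(seq_len(spec$n_classes) - 1L, each = spec$n_samples_per_class)
    x <- matrix(stats::rnorm(n * spec$n_features, sd = spec$noise_sd),
                n, spec$n_features)
    for (i in seq_along(spec$informative_indices)) {
      j <- spec$informative_indices[i]
      k <- (i - 1L) %% spec$n_classes
      x[y == k, j] <- x[y == k, j] + spec$class_mean_shift
    }
    list(x = x, y = y, informative = spec$informative_indices)
  })
}

#' Band power of a signal segment
#'
#' Periodogram power integrated over a frequency band; used to verify the
#' planted ERD (power during imagery divided by baseline power approaches
#' `(1 - erd_depth)^2` when rhythms dominate the band).
#'
#' @param x numeric vector (single-channel segment).
#' @param sfreq sampling rate in Hz.
#' @param band numeric `(low, high)` in Hz.
#' @return total power in the band (arbitrary units).
#' @export
band_power <- function(x, sfreq, band) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  f <- seq(0, n - 1) * sfreq / n
  sel <- f >= band[1] & f <= band[2] & f <= sfreq / 2
  sum(p[sel]) / n
}
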