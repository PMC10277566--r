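# Continuous-signal preprocessing: band-pass filtering, exponential moving
# standardization, decimation, cue-locked epoching. The pipeline order is
# fixed: band-pass -> standardize -> downsample -> epoch; every step is
# channel-wise independent.

#' Band-pass filter a recording
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass applied
#' independently to each channel of the continuous signal. The default band
#' 0.5-40 Hz keeps the mu and beta rhythms that carry motor-imagery
#' information and discards slow drift and high-frequency noise.
#'
#' @param raw a [raw_recording()].
#' @param low,high band edges in Hz; must satisfy `0 < low < high < sfreq/2`.
#' @param order filter order (of the analogue prototype; the zero-phase pass
#'   doubles the effective order).
#' @return The filtered [raw_recording()] (same shape, same events).
#' @export
bandpass <- function(raw, low = 0.5, high = 40, order = 4) {
  stopifnot(inherits(raw, "raw_recording"))
  nyq <- raw$sfreq / 2
  if (!(low > 0 && low < high && high < nyq))
    stop(sprintf("invalid band: need 0 < low < high < %g (Nyquist); got [%g, %g]",
                 nyq, low, high))
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- raw
  for (c in seq_len(nrow(raw$signal)))
    out$signal[c, ] <- signal::filtfilt(bf, raw$signal[c, ])
  out
}

#' Exponential moving standardization
#'
#' Causal running z-scoring of the continuous signal: per channel, an
#' exponentially weighted mean and variance are updated along time
#' (`m_t = (1-a) m_(t-1) + a x_t`, `v_t = (1-a) v_(t-1) + a (x_t - m_t)^2`)
#' and the output is `(x_t - m_t) / max(sqrt(v_t), eps)`. Running statistics
#' are initialized from the first `init_samples` samples.
#'
#' @param raw a [raw_recording()].
#' @param factor_new update factor `a` in (0, 1).
#' @param eps variance floor (applied to the running SD).
#' @param init_samples number of leading samples used to initialize the
#'   running mean and variance.
#' @return The standardized [raw_recording()].
#' @export
ema_standardize <- function(raw, factor_new = 1e-3, eps = 1e-4,
                            init_samples = 1000) {
  stopifnot(inherits(raw, "raw_recording"))
  if (!(factor_new > 0 && factor_new < 1)) stop("factor_new must be in (0, 1)")
  if (eps <= 0) stop("eps must be positive")
  a <- factor_new
  ni <- min(init_samples, ncol(raw$signal))
  out <- raw
  for (c in seq_len(nrow(raw$signal))) {
    x <- raw$signal[c, ]
    m0 <- mean(x[seq_len(ni)])
    v0 <- mean((x[seq_len(ni)] - m0)^2)
    m <- as.numeric(stats::filter(a * x, 1 - a, method = "recursive",
                                  init = m0))
    v <- as.numeric(stats::filter(a * (x - m)^2, 1 - a, method = "recursive",
                                  init = v0))
    out$signal[c, ] <- (x - m) / pmax(sqrt(v), eps)
  }
  out
}

#' Downsample a recording by an integer factor
#'
#' Anti-alias filtered decimation (8th-order Chebyshev type-I low-pass, the
#' standard decimation filter) applied per channel; event sample indices are
#' rescaled by the same factor.
#'
#' @param raw a [raw_recording()].
#' @param target_sfreq target rate in Hz; `sfreq / target_sfreq` must be an
#'   integer.
#' @return The decimated [raw_recording()].
#' @export
downsample <- function(raw, target_sfreq) {
  stopifnot(inherits(raw, "raw_recording"))
  q <- raw$sfreq / target_sfreq
  if (abs(q - round(q)) > 1e-9)
    stop(sprintf("sfreq %g is not an integer multiple of target %g",
                 raw$sfreq, target_sfreq))
  q <- as.integer(round(q))
  if (q == 1L) return(raw)
  n_out <- length(signal::decimate(raw$signal[1, ], q))
  sig <- matrix(0, nrow(raw$signal), n_out)
  for (c in seq_len(nrow(raw$signal)))
    sig[c, ] <- signal::decimate(raw$signal[c, ], q)
  ev <- raw$events
  ev$sample <- ev$sample %/% q
  out <- raw_recording(sig, target_sfreq, ev, raw$channel_names)
  out$meta <- raw$meta
  out
}

#' Cut cue-locked epochs from a recording
#'
#' One epoch per event, spanning `[tmin, tmax)` seconds relative to the cue
#' (tmin inclusive, tmax exclusive), i.e. `round((tmax - tmin) * sfreq)`
#' samples. Events whose window falls outside the recording are dropped with
#' a warning.
#'
#' @param raw a [raw_recording()] with events.
#' @param tmin,tmax epoch window in seconds relative to the cue.
#' @param session session tag carried into the [epoch_set()].
#' @return An [epoch_set()].
#' @export
epoch <- function(raw, tmin = -0.5, tmax = 4, session = "") {
  stopifnot(inherits(raw, "raw_recording"), tmin < tmax)
  if (nrow(raw$events) == 0) stop("recording has no events to epoch")
  ns <- round((tmax - tmin) * raw$sfreq)
  start <- raw$events$sample + round(tmin * raw$sfreq)  # 0-based
  ok <- start >= 0 & (start + ns) <= ncol(raw$signal)
  if (any(!ok))
    warning(sum(!ok), " trial(s) dropped: epoch window outside the recording")
  if (!any(ok)) stop("no trial has a full epoch window inside the recording")
  idx <- which(ok)
  data <- array(0, dim = c(length(idx), nrow(raw$signal), ns))
  for (i in seq_along(idx))
    data[i, , ] <- raw$signal[, start[idx[i]] + seq_len(ns)]
  epoch_set(data, raw$events$label[idx], raw$sfreq, c(tmin, tmax), session)
}

#' Standard preprocessing pipeline
#'
#' Fixed order: band-pass -> exponential moving standardization ->
#' (optional) downsampling -> cue-locked epoching.
#'
#' @param raw a [raw_recording()].
#' @param low,high band-pass edges in Hz.
#' @param target_sfreq target rate in Hz, or `NULL` to keep the native rate.
#' @param tmin,tmax epoch window in seconds relative to the cue.
#' @param session session tag.
#' @return An [epoch_set()].
#' @export
preprocess_recording <- function(raw, low = 0.5, high = 40,
                                 target_sfreq = NULL,
                                 tmin = -0.5, tmax = 4, session = "") {
  raw <- bandpass(raw, low, high)
  raw <- ema_standardize(raw)
  if (!is.null(target_sfreq) && target_sfreq != raw$sfreq)
    raw <- downsample(raw, target_sfreq)
  epoch(raw, tmin, tmax, session)
}
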