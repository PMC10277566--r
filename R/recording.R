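#' Continuous multichannel recording
#'
#' Container for a continuous EEG signal with cue events. Channels are rows,
#' samples are columns. Event sample indices are 0-based (a convention used
#' throughout the package); class labels are 0-based integers.
#'
#' @param signal numeric matrix, channels x samples (microvolt-scale values).
#' @param sfreq sampling frequency in Hz.
#' @param events data.frame with integer columns `sample` (0-based cue onset)
#'   and `label` (0-based class index). May have zero rows.
#' @param channel_names character vector, one name per channel.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(signal, sfreq,
                          events = data.frame(sample = integer(0),
                                              label = integer(0)),
                          channel_names = NULL) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("signal must be a numeric channels x samples matrix")
  if (!is.numeric(sfreq) || length(sfreq) != 1 || sfreq <= 0)
    stop("sfreq must be a single positive number")
  events <- as.data.frame(events)
  if (!all(c("sample", "label") %in% names(events)))
    stop("events needs columns 'sample' and 'label'")
  if (nrow(events) > 0 &&
      (any(events$sample < 0) || any(events$sample >= ncol(signal))))
    stop("event sample indices outside the recording")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(nrow(signal)))
  structure(list(signal = signal, sfreq = sfreq,
                 events = events, channel_names = channel_names),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$signal), ncol(x$signal), x$sfreq, nrow(x$events)))
  invisible(x)
}

#' Epoched trial set
#'
#' Cue-locked trials cut from a continuous recording: a trials x channels x
#' samples array plus per-trial labels.
#'
#' @param data numeric array, trials x channels x samples.
#' @param labels integer vector of 0-based class labels, one per trial.
#' @param sfreq sampling frequency in Hz.
#' @param window numeric length-2 vector `(tmin, tmax)` in seconds relative to
#'   the cue; tmin inclusive, tmax exclusive.
#' @param session free-form session tag (e.g. "train" / "test").
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, sfreq, window, session = "") {
  if (length(dim(data)) != 3) stop("data must be trials x channels x samples")
  labels <- as.integer(labels)
  if (length(labels) != dim(data)[1])
    stop("labels length must equal the number of trials")
  ns_expect <- round((window[2] - window[1]) * sfreq)
  if (dim(data)[3] != ns_expect)
    stop(sprintf("samples (%d) != round((tmax - tmin) * sfreq) = %d",
                 dim(data)[3], ns_expect))
  structure(list(data = data, labels = labels, sfreq = sfreq,
                 window = as.numeric(window), session = session),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set%s> %d trials x %d channels x %d samples @ %g Hz, window [%g, %g) s, %d classes\n",
    if (nzchar(x$session)) paste0(" ", x$session) else "",
    d[1], d[2], d[3], x$sfreq, x$window[1], x$window[2],
    length(unique(x$labels))))
  invisible(x)
}

n_trials <- function(ep) dim(ep$data)[1]

## ---- container serialization ----------------------------------------------
# Objects are stored as a single RDS file plus a JSON sidecar manifest that
# records the class, shapes and key attributes, so runs can be inventoried
# without deserializing.

container_manifest <- function(obj) {
  m <- list(class = class(obj)[1], written = format(Sys.time(), "%Y-%m-%d"))
  if (inherits(obj, "raw_recording")) {
    m$n_channels <- nrow(obj$signal); m$n_samples <- ncol(obj$signal)
    m$sfreq <- obj$sfreq; m$n_events <- nrow(obj$events)
  } else if (inherits(obj, "epoch_set")) {
    d <- dim(obj$data)
    m$n_trials <- d[1]; m$n_channels <- d[2]; m$n_samples <- d[3]
    m$sfreq <- obj$sfreq; m$window <- obj$window; m$session <- obj$session
  } else if (inherits(obj, "relevance_map")) {
    m$dim <- dim(obj$values); m$epsilon <- obj$config$epsilon
    m$target_rule <- obj$config$target_rule
  } else if (inherits(obj, "feature_mask")) {
    m$n_positions <- length(obj$keep); m$n_masked <- sum(!obj$keep)
    m$fraction_masked <- obj$fraction_masked
  } else if (inherits(obj, "importance_profile")) {
    m$n_positions <- length(obj$scores); m$source <- obj$source
  }
  m
}

#' Write / read a package object container
#'
#' Serializes any package object (recording, epoch set, relevance map, mask,
#' importance profile, model) to an RDS file with a JSON sidecar manifest
#' (`<file>.json`) describing shapes and provenance attributes.
#'
#' @param obj object to store.
#' @param file destination path (conventionally `.rds`).
#' @return `write_container` returns `file` invisibly; `read_container`
#'   returns the stored object.
#' @export
write_container <- function(obj, file) {
  dir.create(dirname(file), recursive = TRUE, showWarnings = FALSE)
  saveRDS(obj, file)
  jsonlite::write_json(container_manifest(obj), paste0(file, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_container
#' @export
read_container <- function(file) {
  if (!file.exists(file)) stop("container not found: ", file)
  readRDS(file)
}
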