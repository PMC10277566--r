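# Experiment configuration, dataset-layout adapters, and the end-to-end
# experiment runner behind the command-line script (inst/scripts/lrpselect).

#' Read / write an experiment configuration
#'
#' Configurations are YAML with sections `dataset` (source `"synthetic"`,
#' `"edf_dir"` or `"container"` plus parameters), `preprocessing` (band
#' edges, target rate, epoch window), `run` ([run_spec()] fields) and
#' `output_dir`. Round-trips losslessly.
#'
#' @param file YAML path.
#' @param cfg configuration list.
#' @return `read_experiment_config` returns the configuration list.
#' @export
read_experiment_config <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file)
  cfg <- yaml::read_yaml(file)
  for (f in c("dataset", "run"))
    if (is.null(cfg[[f]])) stop("config is missing the '", f, "' section")
  cfg
}

#' @rdname read_experiment_config
#' @export
write_experiment_config <- function(cfg, file) {
  dir.create(dirname(file), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file)
  invisible(file)
}

#' Default synthetic experiment configuration
#'
#' A balanced four-class synthetic MI preset: 16 channels at 250 Hz, 4-s
#' imagery with planted mu/beta ERD, decimation to 125 Hz in preprocessing,
#' a compact EEGNet training schedule.
#'
#' @param n_trials_per_class trials per class and session.
#' @param seeds run seeds.
#' @return configuration list accepted by [run_experiment()].
#' @export
default_synthetic_config <- function(n_trials_per_class = 40, seeds = 1:3) {
  list(
    dataset = list(source = "synthetic", n_channels = 16, sfreq = 250,
                   n_classes = 4, n_trials_per_class = n_trials_per_class,
                   erd_depth = 0.5, seed = 1),
    preprocessing = list(low = 0.5, high = 40, target_sfreq = 125,
                         tmin = -0.5, tmax = 4),
    run = list(backbone = "eegnet", selector = "lrp", mask_fraction = 0.1,
               backbone_epochs = 30, retrain_epochs = 60,
               batch_size = 72, seeds = seeds),
    output_dir = NULL)
}

synthetic_spec_from_config <- function(ds, seed_offset = 0) {
  args <- ds[setdiff(names(ds), "source")]
  args$seed <- (args$seed %||% 1) + seed_offset
  do.call(synthetic_spec, args)
}

run_spec_from_config <- function(run) {
  run_spec(backbone = run$backbone %||% "eegnet",
           selector = run$selector %||% "lrp",
           mask_fraction = run$mask_fraction %||% 0.1,
           backbone_cfg = train_config(epochs = run$backbone_epochs %||% 200,
                                       batch_size = run$batch_size %||% 72),
           retrain_cfg = train_config(epochs = run$retrain_epochs %||% 100,
                                      batch_size = NA),
           seeds = run$seeds %||% 1:5,
           aggregate = run$aggregate %||% "abs_mean")
}

#' Build the train/test sessions a configuration describes
#'
#' For a synthetic source, generates two independent "sessions" (the test
#' session uses a shifted generator seed) and preprocesses both; for a
#' container source, reads stored epoch sets.
#'
#' @param cfg configuration list (see [read_experiment_config()]).
#' @param seed optional override of the generator base seed.
#' @return list with `train` and `test` [epoch_set()]s.
#' @export
load_sessions <- function(cfg, seed = NULL) {
  ds <- cfg$dataset
  pp <- cfg$preprocessing %||% list()
  prep <- function(raw, tag)
    preprocess_recording(raw, low = pp$low %||% 0.5, high = pp$high %||% 40,
                         target_sfreq = pp$target_sfreq,
                         tmin = pp$tmin %||% -0.5, tmax = pp$tmax %||% 4,
                         session = tag)
  if (ds$source == "synthetic") {
    if (!is.null(seed)) ds$seed <- seed
    tr <- generate_recording(synthetic_spec_from_config(ds, 0))
    te <- generate_recording(synthetic_spec_from_config(ds, 10000))
    list(train = prep(tr, "train"), test = prep(te, "test"))
  } else if (ds$source == "container") {
    list(train = read_container(ds$train), test = read_container(ds$test))
  } else if (ds$source == "edf_dir") {
    subj <- load_edf_sessions(ds$path, prep = prep)
    if (length(subj) == 0) stop("no subjects found in ", ds$path)
    subj[[1]]
  } else stop("unknown dataset source: ", ds$source)
}

#' Run a configured experiment end to end
#'
#' Builds the sessions, runs [run_subject()] (and, when requested,
#' [extremes_experiment()]), and writes a results manifest plus report table
#' into the output directory.
#'
#' @param cfg configuration list or YAML path.
#' @param seed optional base seed overriding both the generator seed and the
#'   run seeds (run seeds become `seed, seed+1, ...` of the same count).
#' @param outdir output directory (overrides `cfg$output_dir`).
#' @param extremes also run the bottom-only / top-only / proposed controls.
#' @return list with `result` (and `extremes` if requested), invisibly;
#'   artifacts under `outdir`.
#' @export
run_experiment <- function(cfg, seed = NULL, outdir = NULL,
                           extremes = FALSE) {
  if (is.character(cfg)) cfg <- read_experiment_config(cfg)
  spec <- run_spec_from_config(cfg$run)
  if (!is.null(seed))
    spec$seeds <- seed + seq_along(spec$seeds) - 1L
  sessions <- load_sessions(cfg, seed)
  res <- run_subject(sessions$train, sessions$test, spec,
                     subject = cfg$subject %||% "S01")
  out <- list(result = res)
  if (extremes) {
    spec_e <- spec
    spec_e$selector <- "lrp"
    out$extremes <- extremes_experiment(sessions$train, sessions$test,
                                        spec_e, cfg$subject %||% "S01")
  }
  outdir <- outdir %||% cfg$output_dir
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    strip <- function(r) r[setdiff(names(r), c("confusion", "mask"))]
    manifest <- list(config = cfg, seeds = spec$seeds,
                     result = strip(res),
                     extremes = if (extremes) lapply(out$extremes, strip))
    jsonlite::write_json(manifest, file.path(outdir, "results.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    utils::write.table(res$confusion,
                       file.path(outdir, "confusion.tsv"), sep = "\t")
    report_tables(c(list(res), if (extremes) unname(out$extremes)),
                  out_file = file.path(outdir, "report.tsv"))
  }
  invisible(out)
}

## ---- dataset-layout adapters ----------------------------------------------

load_edf_sessions <- function(dir, prep) {
  files <- list.files(dir, pattern = "\\.edf$", full.names = TRUE)
  subjects <- unique(sub("_session[12]\\.edf$", "", basename(files)))
  out <- list()
  for (s in subjects) {
    f1 <- file.path(dir, paste0(s, "_session1.edf"))
    f2 <- file.path(dir, paste0(s, "_session2.edf"))
    if (!file.exists(f1) || !file.exists(f2)) {
      warning("subject ", s, " skipped: missing session file")
      next
    }
    out[[s]] <- list(train = prep(read_edf(f1), "train"),
                     test = prep(read_edf(f2), "test"))
  }
  out
}

# common loader core: per-subject session pairs, validated against the
# dataset's published layout (channel count, trial ceiling, class count)
load_mi_dataset <- function(dir, n_channels, max_trials, n_classes,
                            target_sfreq = NULL) {
  prep <- function(raw, tag)
    preprocess_recording(raw, target_sfreq = target_sfreq, session = tag)
  subj <- load_edf_sessions(dir, prep)
  if (length(subj) == 0) stop("no subjects found in ", dir)
  for (s in names(subj)) for (tag in c("train", "test")) {
    ep <- subj[[s]][[tag]]
    d <- dim(ep$data)
    if (d[2] != n_channels)
      warning(sprintf("%s/%s: %d channels, expected %d", s, tag, d[2],
                      n_channels))
    if (d[1] > max_trials)
      warning(sprintf("%s/%s: %d trials exceeds the session ceiling %d",
                      s, tag, d[1], max_trials))
    if (length(unique(ep$labels)) > n_classes)
      warning(sprintf("%s/%s: more than %d classes", s, tag, n_classes))
  }
  subj
}

#' Load a BCI Competition IV-2a style directory
#'
#' Expects per-subject EDF-converted session pairs
#' (`<subject>_session1.edf`, `<subject>_session2.edf`, each with a
#' `.events.csv` sidecar; rejected trials marked with label -1 are excluded
#' on read). Session 1 becomes the training set, session 2 the test set;
#' recordings are band-passed 0.5-40 Hz, standardized and epoched
#' [-0.5, 4) s at the native 250 Hz. Layouts are validated against the
#' published dataset shape (22 channels, <= 288 trials/session, 4 classes).
#'
#' @param dir directory with the session files.
#' @return Named list per subject of `list(train, test)` [epoch_set()]s.
#' @export
load_bci_iv2a <- function(dir) {
  load_mi_dataset(dir, n_channels = 22, max_trials = 288, n_classes = 4)
}

#' Load a KU-MI style directory
#'
#' Same layout as [load_bci_iv2a()]; validated against 62 channels,
#' <= 200 trials/session, 2 classes, with downsampling 1000 -> 250 Hz.
#'
#' @param dir directory with the session files.
#' @return Named list per subject of `list(train, test)` [epoch_set()]s.
#' @export
load_ku_mi <- function(dir) {
  load_mi_dataset(dir, n_channels = 62, max_trials = 200, n_classes = 2,
                  target_sfreq = 250)
}
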