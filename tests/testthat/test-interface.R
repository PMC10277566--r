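# Containers, EDF round-trips, configuration round-trips, loaders and the
# command-line script.

test_that("containers round-trip with a JSON manifest", {
  td <- withr::local_tempdir()
  sp <- synthetic_spec(n_channels = 4, n_trials_per_class = 5, n_classes = 2,
                       trial_duration = 1, inter_trial_interval = 0.5,
                       seed = 2)
  rec <- generate_recording(sp)
  f <- file.path(td, "rec.rds")
  write_container(rec, f)
  expect_true(file.exists(paste0(f, ".json")))
  back <- read_container(f)
  expect_identical(back$signal, rec$signal)
  man <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(man$class, "raw_recording")
  expect_equal(man$n_channels, 4)
  expect_error(read_container(file.path(td, "absent.rds")), "not found")
})

test_that("EDF files round-trip signal, rate and events", {
  td <- withr::local_tempdir()
  set.seed(5)
  sig <- matrix(rnorm(3 * 500, sd = 40), 3)   # 3 channels, 2 s at 250 Hz
  rec <- raw_recording(sig, 250,
                       events = data.frame(sample = c(100L, 300L),
                                           label = c(0L, 1L)),
                       channel_names = c("C3", "C4", "Cz"))
  f <- file.path(td, "rec.edf")
  write_edf(rec, f)
  back <- read_edf(f)
  expect_equal(back$sfreq, 250)
  expect_equal(back$channel_names, c("C3", "C4", "Cz"))
  expect_equal(back$events, rec$events)
  # 16-bit quantization: error bounded by the written physical range / 2^16
  rng <- 2 * max(ceiling(abs(sig)))
  expect_lt(max(abs(back$signal[, 1:500] - sig)), rng / 65536 * 1.01)
  # rejected-trial markers (label -1) are excluded on read
  rec2 <- rec
  rec2$events <- data.frame(sample = c(100L, 200L, 300L),
                            label = c(0L, -1L, 1L))
  f2 <- file.path(td, "rec2.edf")
  class(rec2) <- "raw_recording"
  write_edf(rec2, f2)
  expect_message(back2 <- read_edf(f2), "rejected")
  expect_equal(nrow(back2$events), 2)
})

test_that("our EDF export is readable by an independent reader", {
  td <- withr::local_tempdir()
  set.seed(8)
  sig <- matrix(rnorm(2 * 250, sd = 25), 2)
  rec <- raw_recording(sig, 125, channel_names = c("Fz", "Pz"))
  f <- file.path(td, "x.edf")
  write_edf(rec, f)
  script <- sprintf(paste0(
    "import mne, numpy as np\n",
    "raw = mne.io.read_raw_edf(%s, preload=True, verbose='ERROR')\n",
    "print(int(raw.info['sfreq']))\n",
    "print(','.join(raw.ch_names))\n",
    "print(float(np.max(np.abs(raw.get_data()))))\n"),
    deparse(f))
  out <- system2("python", "-", input = script, stdout = TRUE, stderr = TRUE)
  expect_equal(as.integer(out[1]), 125L)
  expect_equal(out[2], "Fz,Pz")
  # MNE scales EDF physical units (uV) to volts
  expect_equal(as.numeric(out[3]) * 1e6, max(abs(sig)), tolerance = 1e-3)
})

test_that("experiment configs round-trip and validate", {
  td <- withr::local_tempdir()
  cfg <- default_synthetic_config(n_trials_per_class = 10, seeds = 1:2)
  f <- file.path(td, "cfg.yaml")
  write_experiment_config(cfg, f)
  back <- read_experiment_config(f)
  expect_equal(back$dataset$n_channels, cfg$dataset$n_channels)
  expect_equal(back$run$seeds, cfg$run$seeds)
  bad <- cfg; bad$run <- NULL
  f2 <- file.path(td, "bad.yaml")
  write_experiment_config(bad, f2)
  expect_error(read_experiment_config(f2), "'run' section")
  expect_error(read_experiment_config(file.path(td, "none.yaml")),
               "not found")
})

test_that("EDF session directories load as train/test epoch pairs", {
  td <- withr::local_tempdir()
  sp <- synthetic_spec(n_channels = 4, n_trials_per_class = 6, n_classes = 2,
                       trial_duration = 1, inter_trial_interval = 0.5,
                       seed = 4)
  write_edf(generate_recording(sp), file.path(td, "s01_session1.edf"))
  sp$seed <- 5
  write_edf(generate_recording(sp), file.path(td, "s01_session2.edf"))
  prep <- function(raw, tag) preprocess_recording(raw, tmin = 0, tmax = 1,
                                                  session = tag)
  subj <- lrpselect:::load_edf_sessions(td, prep)
  expect_length(subj, 1)
  expect_equal(dim(subj$s01$train$data)[1], 12)
  expect_equal(subj$s01$test$session, "test")
  # a subject missing one session is skipped with a warning
  write_edf(generate_recording(sp), file.path(td, "s02_session1.edf"))
  expect_warning(subj2 <- lrpselect:::load_edf_sessions(td, prep),
                 "skipped")
  expect_length(subj2, 1)
  expect_error(load_bci_iv2a(withr::local_tempdir()), "no subjects")
})

test_that("the command-line script runs simulate and preprocess end to end", {
  td <- withr::local_tempdir()
  script <- system.file("scripts", "lrpselect", package = "lrpselect")
  expect_true(nzchar(script))
  cfgf <- file.path(td, "cfg.yaml")
  cfg <- default_synthetic_config(n_trials_per_class = 4, seeds = 1)
  cfg$dataset$n_channels <- 4
  cfg$dataset$n_classes <- 2
  write_experiment_config(cfg, cfgf)
  rscript <- file.path(R.home("bin"), "Rscript")
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  run <- function(...) {
    suppressWarnings(system2(rscript, c(script, ...), stdout = TRUE,
                             stderr = TRUE, env = env))
  }
  out1 <- run("simulate", "--config", cfgf, "--seed", "1",
              "--out", file.path(td, "rec.rds"))
  expect_true(file.exists(file.path(td, "rec.rds")),
              info = paste(out1, collapse = "\n"))
  out2 <- run("preprocess", "--in", file.path(td, "rec.rds"),
              "--out", file.path(td, "ep.rds"),
              "--target-sfreq", "125")
  expect_true(file.exists(file.path(td, "ep.rds")),
              info = paste(out2, collapse = "\n"))
  ep <- read_container(file.path(td, "ep.rds"))
  expect_s3_class(ep, "epoch_set")
  expect_equal(dim(ep$data)[1], 8)
  # determinism of simulate under the seed flag
  run("simulate", "--config", cfgf, "--seed", "1",
      "--out", file.path(td, "rec2.rds"))
  expect_identical(read_container(file.path(td, "rec.rds"))$signal,
                   read_container(file.path(td, "rec2.rds"))$signal)
})
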