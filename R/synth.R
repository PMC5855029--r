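#' The eight activity-of-daily-living class labels
#'
#' Squat/stand and sit/stand transitions, stair ascent/descent, walking and
#' a fall. These are the target classes of the recognition task.
#'
#' @return Character vector of length 8.
#' @export
activity_classes <- function() {
  c("st-sq", "sq-st", "st-si", "si-st", "s-a", "s-d", "w", "fall")
}

#' Configuration for the synthetic sEMG trial generator
#'
#' The generator emulates the data regime of lower-limb activity monitoring:
#' multi-channel surface EMG sampled at 1000 Hz, roughly two seconds per
#' trial, sensor bandwidth 20-450 Hz, with class-dependent amplitude
#' envelopes and cross-channel envelope coupling.
#'
#' @param n_trials_per_class Trials generated per activity class.
#' @param n_channels Number of EMG channels (muscles); 4 by default,
#'   extensible to 6 for the channel-count experiment.
#' @param separation Non-negative scalar scaling how distinct the class
#'   envelopes are; 0 makes all classes statistically identical.
#' @param snr_db Mean signal-to-noise ratio of added broadband sensor
#'   noise (dB).
#' @param snr_spread_db Range of per-channel SNR offsets (dB), drawn once
#'   per configuration. Real recordings differ in quality across
#'   electrode sites (placement, subcutaneous tissue), which is what the
#'   clustering-based channel weighting exploits; 0 makes channels
#'   homogeneous.
#' @param ar_order Order of the autoregressive colouring of the carrier
#'   innovations.
#' @param duration Trial length in seconds.
#' @param fs Sampling rate in Hz (the band edges 20-450 Hz require
#'   `fs > 950`).
#' @param seed Integer seed; a fixed config yields byte-identical output.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_trials_per_class = 30, n_channels = 4,
                         separation = 1, snr_db = 15, snr_spread_db = 12,
                         ar_order = 4, duration = 2, fs = 1000, seed = 1) {
  if (n_trials_per_class < 1) stopf("n_trials_per_class must be >= 1")
  if (n_channels < 1) stopf("n_channels must be >= 1")
  if (separation < 0) stopf("separation must be >= 0")
  if (snr_spread_db < 0) stopf("snr_spread_db must be >= 0")
  if (ar_order < 0) stopf("ar_order must be >= 0")
  if (fs <= 950) stopf("fs must exceed 950 Hz for a 20-450 Hz pass band")
  if (duration <= 0) stopf("duration must be positive")
  structure(list(n_trials_per_class = as.integer(n_trials_per_class),
                 n_channels = as.integer(n_channels),
                 separation = separation, snr_db = snr_db,
                 snr_spread_db = snr_spread_db,
                 ar_order = as.integer(ar_order), duration = duration,
                 fs = fs, seed = as.integer(seed)),
            class = "synth_config")
}

# Class envelope templates on normalised time tt in [0, 1]. Each class gets
# a fixed shape: ramps for the squat transitions, humps/bursts for the sit
# transitions, 1-2 Hz periodic shapes for stairs and gait, and a sharp
# spike-plus-collapse for the fall. Shapes sit around 1 so that
# `1 + separation * gain * (template - 1)` interpolates towards indistinct
# classes; depths and mean activation levels differ across classes because
# whole-trial features see time-integrated envelope statistics, not the
# raw time course.
envelope_template <- function(cls, tt, duration) {
  switch(cls,
    "st-sq" = 0.5 + 2.6 * tt^1.5,
    "sq-st" = 0.25 + 1.1 * (1 - tt)^2.5,
    "st-si" = 0.35 + 2.1 * (exp(-((tt - 0.3) / 0.1)^2) +
                             exp(-((tt - 0.7) / 0.1)^2)),
    "si-st" = 0.4 + 3.2 * exp(-((tt - 0.5) / 0.11)^2),
    "s-a"  = 1.3 + 1.1 * sin(2 * pi * 1.2 * tt * duration),
    "s-d"  = 0.7 + 0.5 * sin(2 * pi * 1.2 * tt * duration) +
               0.35 * sin(4 * pi * 1.2 * tt * duration + 1),
    "w"    = 1 + 0.85 * sin(2 * pi * 2.3 * tt * duration),
    "fall" = ifelse(tt <= 0.55, 0.4, 0.12) +
               6 * exp(-((tt - 0.5) / 0.018)^2),
    stopf("unknown activity class '%s'", cls)
  )
}

# AR colouring coefficients for the carrier innovations (fixed, stable).
carrier_ar_coefs <- function(order) {
  base <- c(0.5, -0.3, 0.15, -0.05, 0.02, -0.01)
  if (order == 0) return(numeric(0))
  if (order <= length(base)) base[seq_len(order)] else
    c(base, rep(0, order - length(base)))
}

# Skewed, AR-coloured innovation stream: a fraction of the Gaussian
# innovations is replaced by centred squared values so the third-order
# cumulant of the carrier is non-degenerate.
skewed_colored_noise <- function(n, ar_order, skew_fraction = 0.3) {
  burn <- 200
  z <- stats::rnorm(n + burn)
  k <- floor(skew_fraction * (n + burn))
  if (k > 0) {
    idx <- sample.int(n + burn, k)
    z[idx] <- (z[idx]^2 - 1) / sqrt(2)
  }
  if (ar_order > 0)
    z <- as.numeric(stats::filter(z, carrier_ar_coefs(ar_order),
                                  method = "recursive"))
  z <- z[(burn + 1):(burn + n)]
  z / stats::sd(z)
}

# Zero-phase 20-450 Hz band-pass (4th-order Butterworth, forward-backward).
bandpass_20_450 <- function(x, fs) {
  bf <- signal::butter(4, c(20, 450) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

# Smooth positive latent modulation shared by all channels of a trial;
# creates class-independent cross-channel envelope correlation.
shared_latent <- function(n, fs) {
  lf <- signal::butter(2, 3 / (fs / 2), type = "low")
  lat <- signal::filtfilt(lf, stats::rnorm(n + 200))[101:(100 + n)]
  s <- stats::sd(lat)
  if (s < 1e-12) return(rep(1, n))
  pmax(1 + 0.25 * lat / s, 0.05)
}

# Per-(class, channel) envelope gains, drawn once from the config seed.
# The wide spread encodes which muscles an activity recruits and how
# strongly -- the per-channel intensity pattern is a major class cue, as it
# is for real lower-limb ADLs.
channel_gains <- function(cfg, class_index) {
  local_seed(mix_seed(cfg$seed, 7777, class_index),
             stats::runif(cfg$n_channels, 0.45, 1.55))
}

# Per-channel SNR offsets (dB), drawn once per configuration; model
# heterogeneous electrode-site quality.
channel_snr_db <- function(cfg) {
  off <- local_seed(mix_seed(cfg$seed, 8888),
                    stats::runif(cfg$n_channels, -0.5, 0.5))
  cfg$snr_db + cfg$snr_spread_db * off
}

#' Generate one labelled multi-channel sEMG-like trial
#'
#' The per-channel signal is band-limited (20-450 Hz) coloured noise with a
#' skewed innovation stream, amplitude-modulated by a class- and
#' channel-specific envelope plus a latent modulation shared across
#' channels. The fall class contains one abrupt high-amplitude transient;
#' gait and stair classes have periodic envelopes. Broadband noise is added
#' at `cfg$snr_db`.
#'
#' @param cls One of [activity_classes()].
#' @param cfg A [synth_config()].
#' @param trial_index Positive integer identifying the repetition; part of
#'   the deterministic per-trial seed.
#' @return An object of class `semg_trial`: list with `samples` (channels x
#'   T matrix), `fs`, `label`, `subject_id`, `channel_names`.
#' @export
generate_trial <- function(cls, cfg, trial_index = 1) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!cls %in% activity_classes())
    stopf("unknown activity class '%s'", cls)
  ci <- match(cls, activity_classes())
  n <- as.integer(round(cfg$fs * cfg$duration))
  tt <- seq(0, 1, length.out = n)
  tmpl <- envelope_template(cls, tt, cfg$duration)
  gains <- channel_gains(cfg, ci)
  snr_ch <- channel_snr_db(cfg)

  samples <- local_seed(mix_seed(cfg$seed, ci, trial_index), {
    lat <- shared_latent(n, cfg$fs)
    out <- matrix(0, cfg$n_channels, n)
    for (ch in seq_len(cfg$n_channels)) {
      carrier <- bandpass_20_450(
        skewed_colored_noise(n, cfg$ar_order), cfg$fs)
      jitter <- exp(stats::rnorm(1, 0, 0.1))   # trial-to-trial effort
      env <- pmax(1 + cfg$separation * gains[ch] * (tmpl - 1), 0.05) *
        lat * jitter
      x <- carrier * env
      noise_sd <- sqrt(mean(x^2)) * 10^(-snr_ch[ch] / 20)
      out[ch, ] <- 50 * (x + stats::rnorm(n, 0, noise_sd))
    }
    out
  })
  channel_names <- paste0("ch", seq_len(cfg$n_channels))
  rownames(samples) <- channel_names
  structure(list(samples = samples, fs = cfg$fs, label = cls,
                 subject_id = ((trial_index - 1) %% 8) + 1,
                 channel_names = channel_names),
            class = "semg_trial")
}

#' Generate a balanced labelled dataset of synthetic sEMG trials
#'
#' @param cfg A [synth_config()].
#' @return An object of class `semg_dataset`: list with `trials` (list of
#'   [generate_trial()] results) and `manifest` (data frame with columns
#'   `file`, `label`, `subject`, `fs`, one row per trial).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  classes <- activity_classes()
  trials <- vector("list", length(classes) * cfg$n_trials_per_class)
  rows <- list()
  k <- 0
  for (cls in classes) {
    for (ti in seq_len(cfg$n_trials_per_class)) {
      k <- k + 1
      tr <- generate_trial(cls, cfg, ti)
      trials[[k]] <- tr
      rows[[k]] <- data.frame(
        file = sprintf("trial_%03d_%s.csv", k, gsub("-", "_", cls)),
        label = cls, subject = tr$subject_id, fs = cfg$fs,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(trials = trials, manifest = do.call(rbind, rows),
                 config = cfg),
            class = "semg_dataset")
}

#' @export
print.semg_dataset <- function(x, ...) {
  cat(sprintf("<semg_dataset> %d trials, %d channels, %d classes, fs=%g Hz\n",
              length(x$trials), x$config$n_channels,
              length(unique(x$manifest$label)), x$config$fs))
  invisible(x)
}

#' Write a dataset as per-trial CSV files plus a manifest
#'
#' Each trial is written with one column per channel and one row per sample;
#' the manifest (`manifest.csv`) has columns `file`, `label`, `subject`,
#' `fs`.
#'
#' @param ds A [generate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "semg_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ds$trials)) {
    tr <- ds$trials[[i]]
    df <- as.data.frame(t(tr$samples))
    names(df) <- tr$channel_names
    utils::write.csv(df, file.path(dir, ds$manifest$file[i]),
                     row.names = FALSE)
  }
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(ds$manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.csv` and the trial files.
#' @return An object of class `semg_dataset`.
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stopf("no manifest.csv in '%s'", dir)
  man <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  trials <- lapply(seq_len(nrow(man)), function(i) {
    df <- utils::read.csv(file.path(dir, man$file[i]))
    samples <- t(as.matrix(df))
    structure(list(samples = samples, fs = man$fs[i], label = man$label[i],
                   subject_id = man$subject[i],
                   channel_names = rownames(samples)),
              class = "semg_trial")
  })
  structure(list(trials = trials, manifest = man, config = NULL),
            class = "semg_dataset")
}
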