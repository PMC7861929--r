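# Synthetic annotated ECG and labeled feature tables.
#
# Beat model: each heartbeat is the sum of three Gaussian bumps (P, QRS, T)
# at class-specific amplitudes/offsets/widths, so every fiducial has a
# constructible ground truth.  Class caricatures follow the features the
# classifier relies on: V-type beats have a wide QRS, no P wave and an
# inverted T; S-type beats arrive early (short RR) with a small P; F-type
# beats are morphologically intermediate.  Optional sinusoidal baseline
# wander and white noise emulate the dominant ECG noise sources.

.default_wave_params <- list(
  N = list(p = c(amp = 0.15, off = -0.17, sd = 0.025),
           qrs = c(amp = 1.00, off = 0.00, sd = 0.012),
           t = c(amp = 0.35, off = 0.25, sd = 0.060), rr_factor = 1.00),
  S = list(p = c(amp = 0.08, off = -0.12, sd = 0.020),
           qrs = c(amp = 0.95, off = 0.00, sd = 0.012),
           t = c(amp = 0.30, off = 0.22, sd = 0.050), rr_factor = 0.65),
  V = list(p = c(amp = 0.00, off = -0.17, sd = 0.025),
           qrs = c(amp = 1.30, off = 0.00, sd = 0.032),
           t = c(amp = -0.40, off = 0.30, sd = 0.080), rr_factor = 1.00),
  F = list(p = c(amp = 0.08, off = -0.15, sd = 0.022),
           qrs = c(amp = 0.90, off = 0.00, sd = 0.022),
           t = c(amp = 0.20, off = 0.26, sd = 0.060), rr_factor = 0.90))

#' Synthetic-ECG configuration
#'
#' Defaults describe a realistic single-lead recording: 360 Hz sampling,
#' 72 bpm, ~1 mV R amplitude, 0.1 mV baseline wander at 0.3 Hz and 0.02 mV
#' white noise.
#'
#' @param fs sampling rate (Hz).
#' @param n_beats number of beats.
#' @param bpm base heart rate (beats per minute).
#' @param class_sequence per-beat labels over `{N, S, V, F}`; `NULL` means
#'   all `N`.
#' @param wave_params per-class P/QRS/T `(amp mV, off s, sd s)` and
#'   `rr_factor`; see the package default.
#' @param baseline_amp,baseline_freq sinusoidal baseline wander (mV, Hz).
#' @param noise_sd white-noise standard deviation (mV).
#' @param rr_jitter_sd per-beat RR jitter standard deviation (s).
#' @param seed integer seed; generation is reproducible per seed.
#' @return a `synth_ecg_config` list.
#' @export
synth_ecg_config <- function(fs = 360, n_beats = 30L, bpm = 72,
                             class_sequence = NULL,
                             wave_params = .default_wave_params,
                             baseline_amp = 0.1, baseline_freq = 0.3,
                             noise_sd = 0.02, rr_jitter_sd = 0,
                             seed = 1L) {
  assert_scalar_num(fs, "fs", positive = TRUE)
  assert_scalar_num(bpm, "bpm", positive = TRUE)
  n_beats <- as.integer(n_beats)
  if (n_beats < 1L) stop_bad("n_beats must be >= 1")
  if (is.null(class_sequence)) class_sequence <- rep("N", n_beats)
  class_sequence <- as.character(rep_len(class_sequence, n_beats))
  if (!all(class_sequence %in% names(wave_params)))
    stop_bad("class_sequence contains classes without wave_params")
  if (noise_sd < 0 || rr_jitter_sd < 0 || baseline_amp < 0)
    stop_bad("noise/jitter/baseline amplitudes must be nonnegative")
  structure(list(fs = fs, n_beats = n_beats, bpm = bpm,
                 class_sequence = class_sequence, wave_params = wave_params,
                 baseline_amp = baseline_amp, baseline_freq = baseline_freq,
                 noise_sd = noise_sd, rr_jitter_sd = rr_jitter_sd,
                 seed = as.integer(seed)),
            class = "synth_ecg_config")
}

#' Generate an annotated synthetic ECG
#'
#' @param cfg a [synth_ecg_config()].
#' @return list with `signal` (an [ecg_signal()]) and `truth`: a data.frame
#'   of per-beat ground truth (`label`, 0-based `r_index`, and planted
#'   fiducials `p_on .. t_off`; P columns are `NA` where the P amplitude is
#'   zero).  Fiducial on/off truth is center +/- 2.5 wave sd.
#' @export
synth_ecg <- function(cfg = synth_ecg_config()) {
  stopifnot(inherits(cfg, "synth_ecg_config"))
  fs <- cfg$fs
  base_rr <- 60 / cfg$bpm
  with_seed(cfg$seed, {
    r_times <- numeric(cfg$n_beats)
    r_times[1] <- 0.5
    if (cfg$n_beats > 1) {
      for (i in 2:cfg$n_beats) {
        wp <- cfg$wave_params[[cfg$class_sequence[i]]]
        gap <- base_rr * wp$rr_factor
        if (cfg$rr_jitter_sd > 0)
          gap <- max(0.3, gap + stats::rnorm(1, 0, cfg$rr_jitter_sd))
        r_times[i] <- r_times[i - 1] + gap
      }
    }
    dur <- r_times[cfg$n_beats] + 0.6
    n <- ceiling(dur * fs)
    tt <- (seq_len(n) - 1) / fs
    x <- numeric(n)
    for (i in seq_len(cfg$n_beats)) {
      wp <- cfg$wave_params[[cfg$class_sequence[i]]]
      for (wv in c("p", "qrs", "t")) {
        pw <- wp[[wv]]
        if (pw[["amp"]] != 0) {
          c0 <- r_times[i] + pw[["off"]]
          lo <- max(1L, floor((c0 - 5 * pw[["sd"]]) * fs))
          hi <- min(n, ceiling((c0 + 5 * pw[["sd"]]) * fs))
          if (hi >= lo) {
            rng <- lo:hi
            x[rng] <- x[rng] +
              pw[["amp"]] * exp(-((tt[rng] - c0) / pw[["sd"]])^2 / 2)
          }
        }
      }
    }
    if (cfg$baseline_amp > 0)
      x <- x + cfg$baseline_amp * sin(2 * pi * cfg$baseline_freq * tt)
    if (cfg$noise_sd > 0) x <- x + stats::rnorm(n, 0, cfg$noise_sd)
  })
  idx0 <- function(t_s) as.integer(round(t_s * fs))
  tr <- do.call(rbind, lapply(seq_len(cfg$n_beats), function(i) {
    wp <- cfg$wave_params[[cfg$class_sequence[i]]]
    f <- function(wv, what) {
      pw <- wp[[wv]]
      if (pw[["amp"]] == 0) return(NA_integer_)
      c0 <- r_times[i] + pw[["off"]]
      idx0(switch(what, on = c0 - 2.5 * pw[["sd"]], peak = c0,
                  off = c0 + 2.5 * pw[["sd"]]))
    }
    data.frame(label = cfg$class_sequence[i], r_index = idx0(r_times[i]),
               p_on = f("p", "on"), p_peak = f("p", "peak"),
               p_off = f("p", "off"),
               qrs_on = f("qrs", "on"), qrs_off = f("qrs", "off"),
               t_on = f("t", "on"), t_peak = f("t", "peak"),
               t_off = f("t", "off"), stringsAsFactors = FALSE)
  }))
  list(signal = ecg_signal(x, fs = fs,
                           record_id = sprintf("synth%03d", cfg$seed),
                           lead = "synthI"),
       truth = tr, cfg = cfg)
}

#' Annotations data.frame from synthetic ground truth
#'
#' Classes map to representative beat symbols (`N`, `A`, `V`, `F`) so that
#' [map_symbol_to_aami()] recovers the planted labels.
#'
#' @param truth the `truth` data.frame from [synth_ecg()].
#' @return data.frame with `r_index`, `symbol`, `aami_class`.
#' @export
synth_annotations <- function(truth) {
  sym <- c(N = "N", S = "A", V = "V", F = "F")[truth$label]
  data.frame(r_index = truth$r_index, symbol = unname(sym),
             aami_class = truth$label, stringsAsFactors = FALSE)
}

#' Labeled 4-class Gaussian feature table
#'
#' Spherical Gaussian clusters with one mean per class; supports arbitrary
#' class imbalance (e.g. the ~90.6 : 2.8 : 7.2 : 0.8 N:S:V:F imbalance of
#' archival arrhythmia data at reduced n).
#'
#' @param n_per_class named or positional counts for N, S, V, F.
#' @param class_means 4 x d matrix of class means (rows N, S, V, F);
#'   default: orthogonal means separated by 5 units in 5 dimensions.
#' @param spread cluster standard deviation (>= 0).
#' @param seed integer seed.
#' @return list with `X` (matrix) and `labels` (factor over N, S, V, F).
#' @export
synth_feature_table <- function(n_per_class = c(N = 100, S = 100, V = 100,
                                                F = 100),
                                class_means = NULL, spread = 1, seed = 1L) {
  if (length(n_per_class) != 4L) stop_bad("n_per_class must have 4 entries")
  if (spread < 0) stop_bad("spread must be >= 0")
  n_per_class <- stats::setNames(as.integer(n_per_class), AAMI_CLASSES)
  if (is.null(class_means)) {
    class_means <- matrix(0, 4, 5, dimnames = list(AAMI_CLASSES, NULL))
    class_means[2, 1] <- class_means[3, 2] <- class_means[4, 3] <- 5
  }
  d <- ncol(class_means)
  labels <- factor(rep(AAMI_CLASSES, times = n_per_class),
                   levels = AAMI_CLASSES)
  n <- length(labels)
  X <- with_seed(seed, {
    noise <- if (spread > 0) matrix(stats::rnorm(n * d, 0, spread), n, d)
             else matrix(0, n, d)
    class_means[as.integer(labels), , drop = FALSE] + noise
  })
  list(X = X, labels = labels)
}
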