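# P/QRS/T delineation around a detected R peak.
#
# The method is a deterministic slope-threshold search: wave boundaries are
# the first samples, scanning outward from a peak, where the smoothed
# absolute slope falls below a fixed fraction (default 12.5%) of its maximum
# inside the search window.  All window lengths are exposed as parameters.

#' Delineation parameters
#'
#' @param slope_frac boundary threshold as a fraction of the window's maximum
#'   smoothed absolute slope (default 0.125).
#' @param qrs_half_ms half-width of the QRS search window around R (ms).
#' @param t_gap_ms gap after QRS offset before the T search window starts.
#' @param t_end_ms end of the T search window after R (ms).
#' @param p_start_ms,p_end_ms P search window, in ms before QRS onset.
#' @param wave_half_ms half-width of the boundary search around P/T peaks.
#' @param min_amp_mv minimum peak prominence (mV) for a P or T wave to be
#'   considered present.
#' @return a `delineate_params` list.
#' @export
delineate_params <- function(slope_frac = 0.125, qrs_half_ms = 100,
                             t_gap_ms = 60, t_end_ms = 400,
                             p_start_ms = 200, p_end_ms = 20,
                             wave_half_ms = 100, min_amp_mv = 0.05) {
  structure(as.list(environment()), class = "delineate_params")
}

smoothed_abs_slope <- function(x) {
  d <- abs(diff(x))
  moving_avg(c(d, d[length(d)]), 3L)
}

# First index where sslope < thr, scanning in `dir` from the steepest point
# between `peak` and the window edge (the slope at a wave peak is itself near
# zero, so the scan must first pass the flank's slope maximum).
scan_boundary <- function(sslope, peak, dir, lo, hi, thr) {
  flank <- if (dir < 0) lo:peak else peak:hi
  if (length(flank) < 2) return(if (dir < 0) lo else hi)
  from <- flank[which.max(sslope[flank])]
  i <- from
  while (i + dir >= lo && i + dir <= hi) {
    i <- i + dir
    if (sslope[i] < thr) return(i)
  }
  if (dir < 0) lo else hi
}

find_wave <- function(x, sslope, lo, hi, par, polarity = 0) {
  if (hi - lo < 2) return(c(NA_integer_, NA_integer_, NA_integer_))
  w <- x[lo:hi]
  base <- stats::median(w)
  peak <- lo + which.max(abs(w - base)) - 1L
  if (abs(x[peak] - base) < par$min_amp_mv)
    return(c(NA_integer_, NA_integer_, NA_integer_))
  thr <- par$slope_frac * max(sslope[lo:hi])
  on <- scan_boundary(sslope, peak, -1L, lo, hi, thr)
  off <- scan_boundary(sslope, peak, 1L, lo, hi, thr)
  c(on, peak, off)
}

#' Delineate one beat around its R peak
#'
#' Locates QRS onset/offset by the slope-threshold rule within a window
#' around R, then searches for the T peak after the QRS and the P peak before
#' it, with wave boundaries by the same rule.  Fiducials that cannot be
#' found are `NA`.  All indices are 0-based record coordinates, so shifting
#' the signal by k samples shifts every fiducial by exactly k.
#'
#' @param signal a denoised [ecg_signal()].
#' @param r_peak 0-based R sample index.
#' @param prev_r,next_r neighboring 0-based R indices, or `NA`; search
#'   windows are clipped to them when known.
#' @param par a [delineate_params()].
#' @return a named list (class `fiducials`) with `p_on`, `p_peak`, `p_off`,
#'   `qrs_on`, `r_peak`, `qrs_off`, `t_on`, `t_peak`, `t_off` (0-based, `NA`
#'   when missing).  Present fiducials satisfy
#'   `p_on <= p_peak <= p_off <= qrs_on < r_peak < qrs_off <= t_on <= t_peak
#'   <= t_off`.
#' @export
delineate_beat <- function(signal, r_peak, prev_r = NA, next_r = NA,
                           par = delineate_params()) {
  stopifnot(inherits(signal, "ecg_signal"))
  x <- signal$samples
  fs <- signal$fs
  n <- length(x)
  ms <- function(v) round(v / 1000 * fs)
  r <- as.integer(r_peak) + 1L          # to 1-based
  if (r < 2L || r > n - 1L) stop_bad("r_peak outside signal interior")
  sslope <- smoothed_abs_slope(x)

  # QRS on/off
  qlo <- max(1L, r - ms(par$qrs_half_ms))
  qhi <- min(n, r + ms(par$qrs_half_ms))
  if (!is.na(prev_r)) qlo <- max(qlo, as.integer(prev_r) + 2L)
  if (!is.na(next_r)) qhi <- min(qhi, as.integer(next_r))
  thr_l <- par$slope_frac * max(sslope[qlo:r])
  thr_r <- par$slope_frac * max(sslope[r:qhi])
  qrs_on <- scan_boundary(sslope, r, -1L, qlo, qhi, thr_l)
  qrs_off <- scan_boundary(sslope, r, 1L, qlo, qhi, thr_r)
  qrs_on <- min(qrs_on, r - 1L)
  qrs_off <- max(qrs_off, r + 1L)

  # T wave
  tlo <- qrs_off + ms(par$t_gap_ms)
  thi <- min(n, r + ms(par$t_end_ms))
  if (!is.na(next_r)) thi <- min(thi, as.integer(next_r) + 1L - ms(60))
  tw <- if (thi - tlo >= 2 && tlo >= 1)
    find_wave(x, sslope, tlo, thi, par) else rep(NA_integer_, 3)
  if (!is.na(tw[1])) tw[1] <- max(tw[1], qrs_off)

  # P wave
  plo <- max(1L, qrs_on - ms(par$p_start_ms))
  phi <- max(1L, qrs_on - ms(par$p_end_ms))
  if (!is.na(prev_r)) plo <- max(plo, as.integer(prev_r) + 2L)
  pw <- if (phi - plo >= 2)
    find_wave(x, sslope, plo, phi, par) else rep(NA_integer_, 3)
  if (!is.na(pw[3])) pw[3] <- min(pw[3], qrs_on)

  to0 <- function(i) ifelse(is.na(i), NA_integer_, as.integer(i - 1L))
  structure(list(p_on = to0(pw[1]), p_peak = to0(pw[2]), p_off = to0(pw[3]),
                 qrs_on = to0(qrs_on), r_peak = as.integer(r_peak),
                 qrs_off = to0(qrs_off),
                 t_on = to0(tw[1]), t_peak = to0(tw[2]), t_off = to0(tw[3])),
            class = "fiducials")
}

#' Delineate every beat of a segmented record
#'
#' @param signal denoised [ecg_signal()].
#' @param r_indices 0-based R indices (e.g. `beat_set$r_index`).
#' @param par a [delineate_params()].
#' @return list of `fiducials`, one per beat.
#' @export
delineate_record <- function(signal, r_indices, par = delineate_params()) {
  nb <- length(r_indices)
  lapply(seq_len(nb), function(i) {
    delineate_beat(signal, r_indices[i],
                   prev_r = if (i > 1) r_indices[i - 1] else NA,
                   next_r = if (i < nb) r_indices[i + 1] else NA,
                   par = par)
  })
}
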