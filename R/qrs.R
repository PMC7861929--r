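# Pan-Tompkins R-peak detection and detection scoring.
#
# Pipeline: 5-15 Hz band-pass (cascaded 2nd-order Butterworth biquads, applied
# forward-backward for zero phase) -> 5-point derivative -> squaring ->
# 150 ms moving-window integration -> dual adaptive thresholds with 200 ms
# refractory, T-wave discrimination and 1.66*RR search-back; each detection is
# refined to the local absolute maximum of the band-passed signal.

# RBJ biquad coefficients, Q = 1/sqrt(2) (Butterworth)
biquad <- function(type, f0, fs) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / sqrt(2)
  cw <- cos(w0)
  if (type == "low") {
    b <- c((1 - cw) / 2, 1 - cw, (1 - cw) / 2)
  } else {
    b <- c((1 + cw) / 2, -(1 + cw), (1 + cw) / 2)
  }
  a <- c(1 + alpha, -2 * cw, 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

iir2 <- function(coef, x) {
  n <- length(x)
  v <- stats::filter(c(0, 0, x), coef$b, method = "convolution",
                     sides = 1)[2 + seq_len(n)]
  as.numeric(stats::filter(v, -coef$a[2:3], method = "recursive"))
}

filtfilt2 <- function(coef, x) rev(iir2(coef, rev(iir2(coef, x))))

bandpass_5_15 <- function(x, fs) {
  filtfilt2(biquad("high", 5, fs), filtfilt2(biquad("low", 15, fs), x))
}

moving_avg <- function(x, w) {
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - w, 0)
  (cs[seq_len(n) + 1] - cs[lo + 1]) / (seq_len(n) - lo)
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Pan-Tompkins QRS detection
#'
#' @param signal an [ecg_signal()]; `fs >= 100` Hz and at least 2 s of data.
#' @param refractory_s hard minimum distance between detections (default
#'   0.2 s).
#' @return strictly increasing 0-based R-peak sample indices (the convention
#'   used by annotation `r_index`).
#' @export
pan_tompkins <- function(signal, refractory_s = 0.2) {
  stopifnot(inherits(signal, "ecg_signal"))
  fs <- signal$fs
  x <- signal$samples
  if (fs < 100) stop_bad("fs must be >= 100 Hz for QRS detection")
  if (length(x) < 2 * fs) stop_bad("need at least 2 s of signal")
  if (max(x) - min(x) == 0) return(integer(0))

  bp <- bandpass_5_15(x, fs)
  # centered 5-point derivative
  der <- stats::filter(bp, c(1, 2, 0, -2, -1) / 8, sides = 2)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  w_int <- max(2L, round(0.150 * fs))
  mwi <- moving_avg(sq, w_int)
  if (max(mwi) <= 0) return(integer(0))

  refr <- round(refractory_s * fs)
  cand <- local_maxima(mwi)
  cand <- cand[mwi[cand] > 1e-12 * max(mwi)]
  if (!length(cand)) return(integer(0))

  # adaptive thresholds (classic 0.125 / 0.875 running estimates)
  init <- mwi[seq_len(min(length(mwi), 2 * fs))]
  spk <- max(init); npk <- mean(init)
  thr1 <- npk + 0.25 * (spk - npk)
  qrs <- integer(0)
  rr_avg <- fs  # running average RR, init 1 s
  last_slope <- Inf
  slope_at <- function(i) {
    lo <- max(1L, i - w_int); hi <- min(length(sq), i)
    max(abs(der[lo:hi]))
  }
  for (i in cand) {
    accepted <- FALSE
    if (length(qrs) && (i - qrs[length(qrs)]) < refr) next
    # search-back: long gap since the last QRS -> revisit skipped candidates
    # with the lowered threshold thr1/2
    if (length(qrs) && (i - qrs[length(qrs)]) > 1.66 * rr_avg) {
      seg <- cand[cand > qrs[length(qrs)] + refr & cand < i - refr]
      seg <- seg[mwi[seg] > 0.5 * thr1]
      if (length(seg)) {
        j <- seg[which.max(mwi[seg])]
        rr_avg <- 0.875 * rr_avg + 0.125 * (j - qrs[length(qrs)])
        qrs <- c(qrs, j)
        spk <- 0.25 * mwi[j] + 0.75 * spk
        thr1 <- npk + 0.25 * (spk - npk)
      }
    }
    if (mwi[i] > thr1) {
      is_twave <- FALSE
      if (length(qrs) && (i - qrs[length(qrs)]) < round(0.36 * fs))
        is_twave <- slope_at(i) < 0.5 * last_slope
      if (!is_twave) {
        if (length(qrs))
          rr_avg <- 0.875 * rr_avg + 0.125 * (i - qrs[length(qrs)])
        qrs <- c(qrs, i)
        last_slope <- slope_at(i)
        spk <- 0.125 * mwi[i] + 0.875 * spk
        accepted <- TRUE
      }
    }
    if (!accepted) npk <- 0.125 * mwi[i] + 0.875 * npk
    thr1 <- npk + 0.25 * (spk - npk)
  }
  if (!length(qrs)) return(integer(0))

  # refine each integrated-signal peak to the R position on the band-passed
  # signal: search the integration window, then +/- 40 ms around the maximum
  ref40 <- round(0.040 * fs)
  n <- length(bp)
  r <- vapply(qrs, function(i) {
    lo <- max(1L, i - w_int); hi <- min(n, i)
    r0 <- lo + which.max(abs(bp[lo:hi])) - 1L
    lo2 <- max(1L, r0 - ref40); hi2 <- min(n, r0 + ref40)
    as.integer(lo2 + which.max(abs(bp[lo2:hi2])) - 1L)
  }, integer(1))
  r <- sort(unique(r))
  keep <- c(TRUE, diff(r) >= refr)
  while (!all(keep)) {
    r <- r[keep]
    keep <- c(TRUE, diff(r) >= refr)
  }
  as.integer(r - 1L)   # 0-based
}

#' Score detected R peaks against reference annotations
#'
#' Greedy one-to-one nearest matching within a tolerance (default 150 ms, the
#' conventional success window); ties broken toward the earlier reference.
#' Matched pairs are true positives; unmatched detections false positives;
#' unmatched references false negatives.
#'
#' @param detected,reference sorted sample-index vectors (same 0- or 1-based
#'   convention for both).
#' @param fs sampling rate (Hz).
#' @param tol_ms matching tolerance in milliseconds.
#' @return a `detection_score` list: `tp`, `fp`, `fn`, `n_ref`.
#' @export
match_detections <- function(detected, reference, fs, tol_ms = 150) {
  tol <- tol_ms / 1000 * fs
  nd <- length(detected); nr <- length(reference)
  if (nd && nr) {
    dt <- abs(outer(detected, reference, `-`))
    pairs <- which(dt <= tol, arr.ind = TRUE)
    ord <- order(dt[pairs], pairs[, 2], pairs[, 1])
    used_d <- logical(nd); used_r <- logical(nr); tp <- 0L
    for (k in ord) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (!used_d[i] && !used_r[j]) {
        used_d[i] <- used_r[j] <- TRUE
        tp <- tp + 1L
      }
    }
  } else tp <- 0L
  structure(list(tp = tp, fp = nd - tp, fn = nr - tp, n_ref = nr),
            class = "detection_score")
}

#' Detection metrics (Fdr / Se / +p / Acc)
#'
#' `se = 100*tp/(tp+fn)`, `ppv = 100*tp/(tp+fp)`,
#' `fdr = 100*(fp+fn)/n_ref` (false detection rate counts both error kinds
#' against the number of annotated beats) and `acc = 100 - fdr`, so
#' `acc + fdr == 100` identically.
#'
#' @param score a `detection_score` from [match_detections()].
#' @return list with `fdr`, `se`, `ppv`, `acc` (percent); `ppv` is `NA` when
#'   there are no detections.
#' @export
detection_metrics <- function(score) {
  stopifnot(inherits(score, "detection_score"))
  if (score$n_ref <= 0) stop_bad("n_ref must be > 0")
  se <- 100 * score$tp / (score$tp + score$fn)
  ppv <- if (score$tp + score$fp > 0) 100 * score$tp / (score$tp + score$fp)
         else NA_real_
  fdr <- 100 * (score$fp + score$fn) / score$n_ref
  list(fdr = fdr, se = se, ppv = ppv, acc = 100 - fdr)
}
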