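# The ten-feature set: beat morphology (235 samples), wave lengths, timing
# intervals and amplitudes; feature-group combination and min-max
# normalization.

.morph_cols <- sprintf("morph_%03d", 0:234)
.scalar_cols <- c("p_len", "qrs_len", "t_len", "rr_inter", "pr_inter",
                  "st_seg", "qt_inter", "r_amp", "t_amp")

#' Extract the ten features for every segmented beat
#'
#' Per beat: `morph` = the 235 beat samples; wave lengths
#' `p_len = (p_off - p_on)/fs` etc.; `rr_inter = (r - prev_r)/fs` (the
#' record's median RR for the first beat); `pr_inter = (qrs_on - p_on)/fs`;
#' `st_seg = (t_on - qrs_off)/fs`; `qt_inter = (t_off - qrs_on)/fs`;
#' `r_amp` = maximum of the denoised beat; `t_amp` = signed denoised value at
#' the T peak (preserves inverted-T information).  Features depending on a
#' missing fiducial are `NA` (imputed later from training-set medians by
#' [impute_features()]).
#'
#' @param signal denoised [ecg_signal()] (record coordinates for fiducials).
#' @param beat_set a `beat_set` from [segment_beats()].
#' @param fiducials list of `fiducials` from [delineate_record()].
#' @return data.frame with columns `morph_000..morph_234`, the nine scalar
#'   features, and `label`.
#' @export
extract_features <- function(signal, beat_set, fiducials) {
  stopifnot(inherits(beat_set, "beat_set"),
            length(fiducials) == nrow(beat_set$beats))
  fs <- beat_set$fs
  x <- signal$samples
  nb <- nrow(beat_set$beats)
  r <- beat_set$r_index
  rr <- c(NA, diff(r)) / fs
  if (nb > 1) rr[1] <- stats::median(rr[-1])
  sc <- matrix(NA_real_, nb, length(.scalar_cols),
               dimnames = list(NULL, .scalar_cols))
  for (i in seq_len(nb)) {
    f <- fiducials[[i]]
    sc[i, "p_len"] <- (f$p_off - f$p_on) / fs
    sc[i, "qrs_len"] <- (f$qrs_off - f$qrs_on) / fs
    sc[i, "t_len"] <- (f$t_off - f$t_on) / fs
    sc[i, "rr_inter"] <- rr[i]
    sc[i, "pr_inter"] <- (f$qrs_on - f$p_on) / fs
    sc[i, "st_seg"] <- (f$t_on - f$qrs_off) / fs
    sc[i, "qt_inter"] <- (f$t_off - f$qrs_on) / fs
    sc[i, "r_amp"] <- max(beat_set$beats[i, ])
    sc[i, "t_amp"] <- if (!is.na(f$t_peak)) x[f$t_peak + 1L] else NA_real_
  }
  out <- data.frame(beat_set$beats, sc, check.names = FALSE)
  names(out)[seq_len(ncol(beat_set$beats))] <- .morph_cols
  out$label <- beat_set$labels
  out
}

#' Impute missing features with training-set medians
#'
#' @param table feature data.frame from [extract_features()].
#' @param medians named vector of per-column medians to apply; `NULL`
#'   computes them from `train_rows` of `table`.
#' @param train_rows rows used to compute medians (default all).
#' @return list with `table` (imputed), `medians`, and `flags` (logical
#'   matrix marking imputed cells).
#' @export
impute_features <- function(table, medians = NULL,
                            train_rows = seq_len(nrow(table))) {
  cols <- .scalar_cols
  flags <- is.na(as.matrix(table[, cols]))
  if (is.null(medians)) {
    medians <- vapply(cols, function(cn)
      stats::median(table[train_rows, cn], na.rm = TRUE), numeric(1))
    medians[!is.finite(medians)] <- 0
  }
  for (cn in cols) {
    miss <- is.na(table[[cn]])
    if (any(miss)) table[[cn]][miss] <- medians[[cn]]
  }
  list(table = table, medians = medians, flags = flags)
}

#' Feature-group selection
#'
#' Groups follow the fixed concatenation order Morph, Inter, Amp.  The
#' interval group treats the three wave lengths (`p_qrs_t`) as one toggleable
#' unit; its full membership is `{p_qrs_t, rr_inter, pr_inter, st_seg,
#' qt_inter}` (7 columns) and the amplitude group defaults to `{r_amp}`
#' (1 column), so the full selection has 235 + 7 + 1 = 243 columns.
#'
#' @param morph,inter,amp include the group?
#' @param inter_members subset of
#'   `c("p_qrs_t", "rr_inter", "pr_inter", "st_seg", "qt_inter")`.
#' @param amp_members subset of `c("r_amp", "t_amp")`.
#' @return a `feature_selection` list.
#' @export
feature_selection <- function(morph = TRUE, inter = TRUE, amp = TRUE,
                              inter_members = c("p_qrs_t", "rr_inter",
                                                "pr_inter", "st_seg",
                                                "qt_inter"),
                              amp_members = "r_amp") {
  if (!morph && !inter && !amp) stop_bad("at least one group must be selected")
  inter_members <- match.arg(inter_members, several.ok = TRUE)
  amp_members <- match.arg(amp_members, c("r_amp", "t_amp"),
                           several.ok = TRUE)
  structure(list(morph = morph, inter = inter, amp = amp,
                 inter_members = inter_members, amp_members = amp_members),
            class = "feature_selection")
}

selection_columns <- function(sel) {
  cols <- character(0)
  if (sel$morph) cols <- c(cols, .morph_cols)
  if (sel$inter) {
    m <- sel$inter_members
    if ("p_qrs_t" %in% m)
      cols <- c(cols, "p_len", "qrs_len", "t_len")
    cols <- c(cols, intersect(c("rr_inter", "pr_inter", "st_seg",
                                "qt_inter"), m))
  }
  if (sel$amp) cols <- c(cols, sel$amp_members)
  cols
}

#' Assemble the design matrix for a feature-group selection
#'
#' Concatenates the selected groups in fixed order Morph, Inter, Amp.
#'
#' @param table imputed feature data.frame.
#' @param sel a [feature_selection()].
#' @return numeric matrix (beats x dims) with named columns.
#' @export
combine_features <- function(table, sel = feature_selection()) {
  stopifnot(inherits(sel, "feature_selection"))
  cols <- selection_columns(sel)
  as.matrix(table[, cols, drop = FALSE])
}

#' Min-max normalizer fitted on training statistics
#'
#' Scales each dimension to `[0, 1]` using the training minimum and maximum;
#' zero-range dimensions map to 0; out-of-range values at apply time are
#' clipped to `[-0.5, 1.5]`.
#'
#' @param train training matrix.
#' @return a `minmax_normalizer`.
#' @export
fit_normalizer <- function(train) {
  if (!nrow(train)) stop_bad("training matrix is empty")
  structure(list(min = apply(train, 2, min), max = apply(train, 2, max)),
            class = "minmax_normalizer")
}

#' @rdname fit_normalizer
#' @param norm a fitted `minmax_normalizer`.
#' @param X matrix to transform.
#' @export
apply_normalizer <- function(norm, X) {
  if (!inherits(norm, "minmax_normalizer"))
    stop_bad("norm is not a fitted minmax_normalizer")
  rng <- norm$max - norm$min
  out <- sweep(X, 2, norm$min)
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  pmin(pmax(out, -0.5), 1.5)
}
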