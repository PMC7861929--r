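# End-to-end orchestration: preprocess -> R detection/segmentation ->
# delineation -> features -> combine/normalize -> train -> evaluate, plus
# the feature-combination and K sweep harnesses.

#' Pipeline run configuration
#'
#' @param synth a [synth_ecg_config()] used when no records are given.
#' @param records optional character vector of WFDB record paths (annotation
#'   CSV/atr expected alongside); when supplied, replaces synthetic data.
#' @param lead lead name for [read_record()].
#' @param denoise_cfg a [denoise_config()].
#' @param detector `"annotations"` uses annotated R positions;
#'   `"pan_tompkins"` re-detects R peaks and keeps annotated beats matched
#'   within 150 ms.
#' @param selection a [feature_selection()].
#' @param classifier `"dwknn"`, `"knn"` or `"stacking"`.
#' @param k,const DWKNN hyperparameters for `"dwknn"`/`"knn"`.
#' @param stacking a [stacking_config()] for `"stacking"`.
#' @param train_frac training fraction for the stratified split.
#' @param seed integer seed driving the split (and stacking folds unless the
#'   stacking config sets its own).
#' @param out_dir optional directory for report artifacts.
#' @return a `run_config` list.
#' @export
run_config <- function(synth = synth_ecg_config(),
                       records = NULL, lead = NULL,
                       denoise_cfg = denoise_config(),
                       detector = c("annotations", "pan_tompkins"),
                       selection = feature_selection(),
                       classifier = c("dwknn", "knn", "stacking"),
                       k = 4L, const = 1,
                       stacking = NULL,
                       train_frac = 0.9, seed = 1L, out_dir = NULL) {
  detector <- match.arg(detector)
  classifier <- match.arg(classifier)
  if (is.null(stacking))
    stacking <- stacking_config(seed = seed)
  structure(list(synth = synth, records = records, lead = lead,
                 denoise_cfg = denoise_cfg, detector = detector,
                 selection = selection, classifier = classifier,
                 k = as.integer(k), const = const, stacking = stacking,
                 train_frac = train_frac, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

# load or synthesize records; returns list of (signal, annotations)
pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$records)) {
    lapply(cfg$records, function(p) {
      base <- sub("\\.hea$", "", p)
      ann_path <- if (file.exists(paste0(base, ".csv")))
        paste0(base, ".csv") else paste0(base, ".atr")
      list(signal = read_record(p, cfg$lead),
           annotations = read_annotations(ann_path))
    })
  } else {
    s <- synth_ecg(cfg$synth)
    list(list(signal = s$signal, annotations = synth_annotations(s$truth)))
  }
}

# full feature table for one record
record_features <- function(signal, ann, cfg) {
  den <- denoise(signal, cfg$denoise_cfg)
  ann <- ann[ann$aami_class %in% AAMI_CLASSES, , drop = FALSE]
  if (cfg$detector == "pan_tompkins") {
    det <- pan_tompkins(den)
    tol <- 0.150 * den$fs
    near <- vapply(ann$r_index, function(r) {
      d <- abs(det - r)
      if (length(d) && min(d) <= tol) det[which.min(d)] else NA_integer_
    }, integer(1))
    ann <- ann[!is.na(near), , drop = FALSE]
    ann$r_index <- near[!is.na(near)]
    ann <- ann[order(ann$r_index), , drop = FALSE]
    ann <- ann[!duplicated(ann$r_index), , drop = FALSE]
  }
  bs <- segment_beats(den, ann)
  fid <- delineate_record(den, bs$r_index)
  extract_features(den, bs, fid)
}

#' Run the full classification pipeline
#'
#' Executes preprocessing, beat segmentation, delineation, feature
#' extraction, combination and normalization, a stratified train/test split,
#' classifier training and four-class evaluation.
#'
#' @param cfg a [run_config()].
#' @return list with `confusion`, `report`, `overall_accuracy`, `n_train`,
#'   `n_test`, `model`, `config`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  inputs <- pipeline_inputs(cfg)
  tabs <- lapply(inputs, function(rec)
    record_features(rec$signal, rec$annotations, cfg))
  table <- do.call(rbind, tabs)
  fit_eval(table, cfg)
}

# split / impute / normalize / train / evaluate a feature table
fit_eval <- function(table, cfg) {
  labels <- table$label
  split <- split_dataset(labels, cfg$train_frac, cfg$seed)
  imp <- impute_features(table, train_rows = split$train_ids)
  X <- combine_features(imp$table, cfg$selection)
  norm <- fit_normalizer(X[split$train_ids, , drop = FALSE])
  Xtr <- apply_normalizer(norm, X[split$train_ids, , drop = FALSE])
  Xte <- apply_normalizer(norm, X[split$test_ids, , drop = FALSE])
  ytr <- labels[split$train_ids]
  yte <- labels[split$test_ids]
  model <- switch(cfg$classifier,
    dwknn = dwknn(Xtr, ytr, k = cfg$k, const = cfg$const),
    knn = dwknn(Xtr, ytr, k = cfg$k, const = cfg$const, weighted = FALSE),
    stacking = fit_stacking(Xtr, ytr, cfg$stacking))
  pred <- predict(model, Xte)
  cm <- confusion_matrix(yte, pred)
  rep <- classification_report(cm)
  res <- list(confusion = cm, report = rep,
              overall_accuracy = overall_accuracy(cm),
              n_train = length(split$train_ids),
              n_test = length(split$test_ids),
              model = model, config = cfg)
  if (!is.null(cfg$out_dir)) write_artifacts(res, cfg$out_dir)
  res
}

write_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_confusion_csv(res$confusion, file.path(out_dir, "confusion.csv"))
  utils::write.csv(res$report, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(overall_accuracy = res$overall_accuracy,
         n_train = res$n_train, n_test = res$n_test,
         classifier = res$config$classifier, seed = res$config$seed),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Accuracy sweep over feature-group combinations
#'
#' All combinations share one frozen split and feature table per seed, so
#' results are comparable and byte-reproducible.
#'
#' @param cfg a [run_config()].
#' @param combos list of [feature_selection()] objects.
#' @return data.frame with columns `combo` and `accuracy` (percent,
#'   2 decimals).
#' @export
sweep_feature_combinations <- function(cfg, combos) {
  if (!length(combos)) stop_bad("combos must be non-empty")
  inputs <- pipeline_inputs(cfg)
  table <- do.call(rbind, lapply(inputs, function(rec)
    record_features(rec$signal, rec$annotations, cfg)))
  acc <- vapply(combos, function(sel) {
    c2 <- cfg
    c2$selection <- sel
    c2$out_dir <- NULL
    round_half_up(fit_eval(table, c2)$overall_accuracy)
  }, numeric(1))
  name <- vapply(combos, function(sel)
    paste(c("morph", "inter", "amp")[c(sel$morph, sel$inter, sel$amp)],
          collapse = "+"), character(1))
  data.frame(combo = name, accuracy = acc, stringsAsFactors = FALSE)
}

#' Accuracy sweep over K
#'
#' @param cfg a [run_config()] (classifier `"dwknn"` or `"knn"`).
#' @param ks integer vector of neighbor counts.
#' @return data.frame with columns `k` and `accuracy`.
#' @export
sweep_k <- function(cfg, ks) {
  if (!length(ks)) stop_bad("ks must be non-empty")
  inputs <- pipeline_inputs(cfg)
  table <- do.call(rbind, lapply(inputs, function(rec)
    record_features(rec$signal, rec$annotations, cfg)))
  acc <- vapply(ks, function(k) {
    c2 <- cfg
    c2$k <- as.integer(k)
    c2$out_dir <- NULL
    round_half_up(fit_eval(table, c2)$overall_accuracy)
  }, numeric(1))
  data.frame(k = as.integer(ks), accuracy = acc)
}
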