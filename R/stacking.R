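# Stacking ensemble of DWKNN base learners.
#
# First layer: S DWKNN configurations, each trained per fold on the
# out-of-fold data of a stratified n-fold partition of the training set; the
# out-of-fold predictions, one-hot encoded, form the meta-features.  Second
# layer: a DWKNN meta-classifier on those meta-features.  At test time each
# configuration's n fold-models predict the test rows; their one-hot outputs
# are averaged uniformly into the test meta-feature block.

#' Stacking configuration
#'
#' @param base_params list of `(k, const)` lists for the first-layer DWKNNs
#'   (default four learners, k = 3..6, const = 1).
#' @param n_folds number of cross-training folds (default 10).
#' @param seed integer seed for the stratified fold assignment.
#' @param meta_params `(k, const)` for the DWKNN meta-classifier.
#' @return a `stacking_config` list.
#' @export
stacking_config <- function(base_params = lapply(3:6, function(k)
                              list(k = k, const = 1)),
                            n_folds = 10L, seed = 1L,
                            meta_params = list(k = 4, const = 1)) {
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop_bad("n_folds must be >= 2")
  if (!length(base_params)) stop_bad("base_params must be non-empty")
  structure(list(base_params = base_params, n_folds = n_folds,
                 seed = as.integer(seed), meta_params = meta_params),
            class = "stacking_config")
}

# stratified fold ids: within each class, shuffled round-robin assignment
stratified_folds <- function(y, n_folds, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      ids <- which(y == cls)
      ids <- ids[sample.int(length(ids))]
      fold[ids] <- rep_len(seq_len(n_folds), length(ids))
    }
  })
  fold
}

one_hot <- function(labels, classes) {
  m <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  m[cbind(seq_along(labels), match(as.character(labels), classes))] <- 1
  m
}

#' Fit a Stacking-DWKNN ensemble
#'
#' @param X training matrix (normalized features).
#' @param y training labels.
#' @param cfg a [stacking_config()].
#' @return object of class `stacking_model` with `fold_models`
#'   (`n_folds` x S), `meta_model`, `fold_assignment`, `classes`.
#' @export
fit_stacking <- function(X, y, cfg = stacking_config()) {
  stopifnot(inherits(cfg, "stacking_config"))
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < cfg$n_folds) stop_bad("need at least n_folds training rows")
  classes <- class_levels_for(y)
  y <- factor(as.character(y), levels = classes)
  fold <- stratified_folds(y, cfg$n_folds, cfg$seed)
  if (any(tabulate(fold, cfg$n_folds) == 0L))
    stop_bad("a fold received zero rows; reduce n_folds")
  S <- length(cfg$base_params)
  nc <- length(classes)
  meta <- matrix(0, n, S * nc)
  fold_models <- vector("list", cfg$n_folds)
  for (f in seq_len(cfg$n_folds)) {
    in_fold <- fold == f
    fold_models[[f]] <- vector("list", S)
    for (s in seq_len(S)) {
      p <- cfg$base_params[[s]]
      m <- dwknn(X[!in_fold, , drop = FALSE], y[!in_fold],
                 k = p$k, const = p$const %||% 1)
      fold_models[[f]][[s]] <- m
      oof <- predict(m, X[in_fold, , drop = FALSE])
      meta[in_fold, (s - 1) * nc + seq_len(nc)] <- one_hot(oof, classes)
    }
  }
  meta_model <- dwknn(meta, y, k = cfg$meta_params$k,
                      const = cfg$meta_params$const %||% 1)
  structure(list(fold_models = fold_models, meta_model = meta_model,
                 fold_assignment = fold, classes = classes, cfg = cfg,
                 d = ncol(X)),
            class = "stacking_model")
}

#' @export
print.stacking_model <- function(x, ...) {
  cat(sprintf("<stacking_model> %d base configs x %d folds, meta k = %d\n",
              length(x$cfg$base_params), x$cfg$n_folds, x$meta_model$k))
  invisible(x)
}

#' Predict with a Stacking-DWKNN ensemble
#'
#' For each base configuration the fold-models' one-hot predictions are
#' averaged with uniform weights into that configuration's meta-feature
#' block; the concatenated blocks feed the meta-classifier.
#'
#' @param object a `stacking_model`.
#' @param newdata query matrix.
#' @param ... unused.
#' @return factor of predicted labels.
#' @export
predict.stacking_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d)
    stop_bad("query has ", ncol(newdata), " columns; model expects ", object$d)
  n <- nrow(newdata)
  nc <- length(object$classes)
  S <- length(object$cfg$base_params)
  nf <- object$cfg$n_folds
  meta <- matrix(0, n, S * nc)
  for (s in seq_len(S)) {
    blk <- matrix(0, n, nc)
    for (f in seq_len(nf))
      blk <- blk + one_hot(predict(object$fold_models[[f]][[s]], newdata),
                           object$classes)
    meta[, (s - 1) * nc + seq_len(nc)] <- blk / nf
  }
  predict(object$meta_model, meta)
}
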