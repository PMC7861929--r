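# Distance-weighted k-nearest-neighbor classifier.
#
# Each of the k nearest training points (Euclidean distance) contributes
# weight w_i = 1 / (d_i + const) to its own label's tally; the predicted
# class is the argmax of the tallies.  With weighted = FALSE all weights are
# 1 and the classifier reduces to plain majority-vote KNN.  Determinism:
# distance ties at the k-th neighbor keep the lowest training index; vote
# ties break by the fixed class order (N, S, V, F for AAMI labels).

#' Inverse-distance neighbor weights
#'
#' `w_i = 1 / (d_i + const)`: strictly decreasing in distance, bounded by
#' `1/const`, finite at zero distance.
#'
#' @param distances nonnegative distances.
#' @param const positive weight offset.
#' @return weights, one per distance.
#' @export
neighbor_weights <- function(distances, const) {
  assert_scalar_num(const, "const", positive = TRUE)
  if (any(distances < 0)) stop_bad("distances must be nonnegative")
  1 / (distances + const)
}

class_levels_for <- function(y) {
  u <- unique(as.character(y))
  if (all(u %in% AAMI_CLASSES)) AAMI_CLASSES else sort(u)
}

#' Fit (store) a DWKNN model
#'
#' A lazy learner: the training matrix and labels are stored verbatim.
#'
#' @param X training matrix (rows = observations), typically normalized.
#' @param y labels; AAMI labels get the fixed level order N, S, V, F,
#'   anything else lexicographic.
#' @param k neighbor count (default 4, the value at which accuracy peaks in
#'   K sweeps on the reference benchmark).
#' @param const weight offset (default 1).
#' @param weighted if `FALSE`, plain unweighted KNN voting.
#' @return object of class `dwknn`.
#' @export
dwknn <- function(X, y, k = 4L, const = 1, weighted = TRUE) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop_bad("length(y) must equal nrow(X)")
  k <- as.integer(k)
  if (k < 1L) stop_bad("k must be >= 1")
  if (k > nrow(X)) stop_bad("k (", k, ") exceeds training size (", nrow(X), ")")
  assert_scalar_num(const, "const", positive = TRUE)
  lv <- class_levels_for(y)
  structure(list(X = X, y = factor(as.character(y), levels = lv),
                 k = k, const = const, weighted = isTRUE(weighted),
                 classes = lv, x2 = rowSums(X^2)),
            class = "dwknn")
}

#' @export
print.dwknn <- function(x, ...) {
  cat(sprintf("<dwknn> n = %d, d = %d, k = %d, const = %g%s\n",
              nrow(x$X), ncol(x$X), x$k, x$const,
              if (x$weighted) "" else " (unweighted)"))
  invisible(x)
}

# per-query class weight tallies; newdata is a matrix block
dwknn_tallies <- function(object, newdata) {
  q2 <- rowSums(newdata^2)
  # squared distances via the inner-product expansion, clipped at 0
  d2 <- outer(q2, object$x2, `+`) - 2 * tcrossprod(newdata, object$X)
  d2[d2 < 0] <- 0
  nc <- length(object$classes)
  tallies <- matrix(0, nrow(newdata), nc,
                    dimnames = list(NULL, object$classes))
  yi <- as.integer(object$y)
  for (i in seq_len(nrow(newdata))) {
    nn <- order(d2[i, ])[seq_len(object$k)]    # stable: ties keep low index
    w <- if (object$weighted) neighbor_weights(sqrt(d2[i, nn]), object$const)
         else rep(1, object$k)
    for (j in seq_along(nn))
      tallies[i, yi[nn[j]]] <- tallies[i, yi[nn[j]]] + w[j]
  }
  tallies
}

#' Predict with a DWKNN model
#'
#' @param object a [dwknn()] model.
#' @param newdata query matrix (or single vector); column count must match
#'   training.
#' @param type `"class"` for labels; `"detail"` additionally returns the
#'   per-class vote weights.
#' @param block rows per distance block (memory control).
#' @param ... unused.
#' @return factor of predicted labels, or for `type = "detail"` a list with
#'   `label` and `class_weights`.
#' @export
predict.dwknn <- function(object, newdata, type = c("class", "detail"),
                          block = 1024L, ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$X))
    stop_bad("query has ", ncol(newdata), " columns; model expects ",
             ncol(object$X))
  n <- nrow(newdata)
  if (n == 0L) {
    labs <- factor(character(0), levels = object$classes)
    return(if (type == "class") labs
           else list(label = labs,
                     class_weights = matrix(0, 0, length(object$classes))))
  }
  tallies <- matrix(0, n, length(object$classes),
                    dimnames = list(NULL, object$classes))
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(n, start + block - 1L)
    tallies[rows, ] <- dwknn_tallies(object, newdata[rows, , drop = FALSE])
  }
  labs <- factor(object$classes[max.col(tallies, ties.method = "first")],
                 levels = object$classes)
  if (type == "class") labs else list(label = labs, class_weights = tallies)
}

#' Row-wise batch prediction
#'
#' Order-preserving convenience wrapper around [predict.dwknn()].
#'
#' @param model a [dwknn()] model.
#' @param X_query query matrix.
#' @return factor of predicted labels, one per row.
#' @export
predict_batch <- function(model, X_query) predict(model, X_query)
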