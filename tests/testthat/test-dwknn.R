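# brute-force oracle: exhaustive neighbor search + weighted vote tally
oracle_dwknn <- function(X, y, k, const, q, weighted = TRUE) {
  d <- sqrt(colSums((t(X) - q)^2))
  nn <- order(d)[seq_len(k)]
  w <- if (weighted) 1 / (d[nn] + const) else rep(1, k)
  classes <- if (all(unique(as.character(y)) %in% c("N", "S", "V", "F")))
    c("N", "S", "V", "F") else sort(unique(as.character(y)))
  tally <- vapply(classes, function(cl) sum(w[as.character(y)[nn] == cl]),
                  numeric(1))
  classes[which.max(tally)]
}

test_that("neighbor_weights evaluates the inverse-distance formula", {
  expect_equal(neighbor_weights(c(0.4, 0.6, 1.6), 0.1),
               c(2.0, 1.4285714285714286, 0.5882352941176471),
               tolerance = 1e-12)
  expect_equal(neighbor_weights(c(0, 0), 1), c(1, 1))
  # huge const degenerates to uniform weights
  w <- neighbor_weights(c(0.1, 5, 100), 1e9)
  expect_lt(diff(range(w)) / w[1], 1e-6)
  expect_error(neighbor_weights(c(1, 2), 0), "const")
  expect_error(neighbor_weights(c(-1), 1), "nonnegative")
})

test_that("fit validates and stores verbatim", {
  X <- matrix(rnorm(20), 10)
  y <- rep(c("N", "V"), 5)
  m <- dwknn(X, y, k = 3)
  expect_equal(m$X, X)
  expect_equal(as.character(m$y), y)
  expect_error(dwknn(X, y, k = 0), "k must be")
  expect_error(dwknn(X, y, k = 11), "exceeds")
  expect_no_error(dwknn(X, y, k = 10))   # k = n boundary
  expect_error(dwknn(X, y[-1]), "length")
  expect_error(dwknn(X, y, const = -1), "const")
})

test_that("hand-worked vote example predicts the heavier class", {
  X <- matrix(c(0, 1, 2), ncol = 1)
  y <- c("X", "Y", "Y")
  m <- dwknn(X, y, k = 3, const = 0.1)
  det <- predict(m, matrix(0.4), type = "detail")
  expect_equal(unname(det$class_weights[1, "X"]), 2.0, tolerance = 1e-12)
  expect_equal(unname(det$class_weights[1, "Y"]), 1.4285714 + 0.5882353,
               tolerance = 1e-6)
  expect_equal(as.character(det$label), "Y")
})

test_that("k = 1 returns the nearest label; constant labels dominate", {
  set.seed(2)
  X <- matrix(rnorm(30), 15)
  y <- sample(c("N", "S", "V"), 15, replace = TRUE)
  m1 <- dwknn(X, y, k = 1)
  q <- X[7, ] + 1e-9
  expect_equal(as.character(predict(m1, q)), y[7])
  # leave-one-out self-prediction with k = 1 on distinct points
  expect_equal(as.character(predict(m1, X)), y)
  mall <- dwknn(X, rep("V", 15), k = 5)
  expect_true(all(predict(mall, matrix(rnorm(10 * 2), 10)) == "V"))
})

test_that("dwknn equals the brute-force oracle on 200 random instances", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(5:50, 1); d <- sample(1:5, 1)
    X <- matrix(rnorm(n * d), n)
    y <- sample(c("N", "S", "V", "F"), n, replace = TRUE)
    k <- sample(1:min(8, n), 1)
    const <- runif(1, 0.05, 2)
    q <- rnorm(d)
    m <- dwknn(X, y, k = k, const = const)
    expect_equal(as.character(predict(m, q)),
                 oracle_dwknn(X, y, k, const, q))
  }
})

test_that("const -> Inf limit equals unweighted majority vote", {
  # the limit statement holds where the majority vote is unique (a count
  # tie is broken by the vanishing distance term in the limit, by class
  # order in the unweighted vote)
  set.seed(23)
  checked <- 0
  for (i in 1:80) {
    n <- 30; d <- 3
    X <- matrix(rnorm(n * d), n)
    y <- sample(c("N", "S", "V", "F"), n, replace = TRUE)
    q <- rnorm(d)
    dists <- sqrt(colSums((t(X) - q)^2))
    counts <- table(factor(y[order(dists)[1:5]], c("N", "S", "V", "F")))
    if (sum(counts == max(counts)) > 1) next
    checked <- checked + 1
    big <- dwknn(X, y, k = 5, const = 1e9)
    expect_equal(as.character(predict(big, q)),
                 oracle_dwknn(X, y, 5, 1, q, weighted = FALSE))
    unw <- dwknn(X, y, k = 5, weighted = FALSE)
    expect_equal(as.character(predict(unw, q)),
                 as.character(predict(big, q)))
  }
  expect_gte(checked, 30)
})

test_that("batch prediction is the row-wise loop, order-preserving", {
  set.seed(5)
  X <- matrix(rnorm(60 * 4), 60)
  y <- sample(c("N", "S", "V", "F"), 60, replace = TRUE)
  m <- dwknn(X, y, k = 4)
  Q <- matrix(rnorm(100 * 4), 100)
  batch <- predict_batch(m, Q)
  loop <- vapply(seq_len(nrow(Q)), function(i)
    as.character(predict(m, Q[i, ])), character(1))
  expect_equal(as.character(batch), loop)
  # permutation equivariance
  p <- sample(100)
  expect_equal(as.character(predict(m, Q[p, ])), loop[p])
  # empty query
  expect_length(predict(m, Q[0, , drop = FALSE]), 0)
  expect_error(predict(m, Q[, 1:3]), "columns")
})
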