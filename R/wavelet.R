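# Orthogonal wavelet machinery: Daubechies filter bank, periodized DWT/IDWT,
# thresholding, and a continuous wavelet transform by direct discretized
# convolution.  Self-contained: filter constants were generated by spectral
# factorization of the Daubechies half-band polynomial and match the standard
# published values; orthonormality and perfect reconstruction are enforced by
# the test suite.

.db_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db4 = c(2.3037781330889612e-01, 7.1484657055291467e-01,
          6.3088076792985859e-01, -2.7983769416858730e-02,
          -1.8703481171909236e-01, 3.0841381835560702e-02,
          3.2883011666885113e-02, -1.0597401785069000e-02),
  db6 = c(1.1154074335010924e-01, 4.9462389039845295e-01,
          7.5113390802109792e-01, 3.1525035170920335e-01,
          -2.2626469396543619e-01, -1.2976686756726596e-01,
          9.7501605587318033e-02, 2.7522865530303833e-02,
          -3.1582039317486155e-02, 5.5384220116135182e-04,
          4.7772575109454535e-03, -1.0773010853084640e-03))

#' Orthonormal scaling (low-pass) filter for a named wavelet
#'
#' @param name one of `"haar"`, `"db4"`, `"db6"`.
#' @return numeric filter coefficients summing to `sqrt(2)`.
#' @export
wavelet_filter <- function(name) {
  h <- .db_filters[[name]]
  if (is.null(h)) stop_bad("unknown wavelet: ", name,
                           " (have: ", paste(names(.db_filters),
                                             collapse = ", "), ")")
  h
}

# quadrature mirror high-pass from low-pass
qmf <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1)
}

dwt_step <- function(x, h, g) {
  N <- length(x)
  L <- length(h)
  half <- N %/% 2L
  # circular indexing: y[k] = sum_n filt[n] x[(2k + n) mod N], k = 0..N/2-1
  idx <- outer(2L * (seq_len(half) - 1L), seq_len(L) - 1L, `+`) %% N + 1L
  xm <- matrix(x[idx], nrow = half)
  list(a = as.vector(xm %*% h), d = as.vector(xm %*% g))
}

idwt_step <- function(a, d, h, g) {
  half <- length(a)
  N <- 2L * half
  L <- length(h)
  x <- numeric(N)
  pos <- outer(2L * (seq_len(half) - 1L), seq_len(L) - 1L, `+`) %% N + 1L
  for (n in seq_len(L)) {
    p <- pos[, n]
    x[p] <- x[p] + h[n] * a + g[n] * d
  }
  x
}

#' Periodized orthogonal discrete wavelet transform
#'
#' Circular-convolution pyramid transform.  The analysis operator is
#' orthonormal, so [idwt_periodic()] (its transpose) reconstructs exactly.
#'
#' @param x numeric vector; `length(x)` must be divisible by `2^levels`.
#' @param wavelet wavelet name, see [wavelet_filter()].
#' @param levels decomposition depth.
#' @return list with `approx` (coarsest approximation) and `details`
#'   (list of detail vectors, level 1 = finest).
#' @export
dwt_periodic <- function(x, wavelet = "db6", levels = 1L) {
  h <- wavelet_filter(wavelet)
  g <- qmf(h)
  if (length(x) %% 2^levels != 0)
    stop_bad("length(x) must be divisible by 2^levels")
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a, h, g)
    details[[j]] <- s$d
    a <- s$a
  }
  structure(list(approx = a, details = details, wavelet = wavelet,
                 levels = levels, n = length(x)),
            class = "dwt_coeffs")
}

#' Inverse periodized orthogonal DWT
#'
#' @param coeffs a `dwt_coeffs` object from [dwt_periodic()].
#' @return reconstructed numeric vector.
#' @export
idwt_periodic <- function(coeffs) {
  h <- wavelet_filter(coeffs$wavelet)
  g <- qmf(h)
  a <- coeffs$approx
  for (j in rev(seq_len(coeffs$levels)))
    a <- idwt_step(a, coeffs$details[[j]], h, g)
  a
}

#' Soft / hard thresholding
#'
#' @param x numeric vector.
#' @param t nonnegative threshold.
#' @return thresholded vector.
#' @export
soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' @rdname soft_threshold
#' @export
hard_threshold <- function(x, t) ifelse(abs(x) > t, x, 0)

# Mexican-hat (Ricker) mother wavelet, unit scale
ricker <- function(t) (2 / (sqrt(3) * pi^0.25)) * (1 - t^2) * exp(-t^2 / 2)

#' Continuous wavelet transform by discretized convolution
#'
#' Computes `W(m, tau) = m^(-1/2) * sum_t f(t) psi((t - tau)/m) * dt` for each
#' scale `m`, i.e. the CWT integral discretized at the sampling grid, with a
#' single shift parameter `tau` running over every sample.
#'
#' @param signal an [ecg_signal()] or numeric vector.
#' @param scales positive scale factors, in samples.
#' @param mother mother wavelet: `"mexh"` (Mexican hat).
#' @return matrix with one row per scale, one column per sample.
#' @export
wavelet_transform <- function(signal, scales, mother = "mexh") {
  x <- if (inherits(signal, "ecg_signal")) signal$samples else as.numeric(signal)
  if (!all(is.finite(x))) stop_bad("signal contains non-finite samples")
  if (!length(scales) || any(scales <= 0))
    stop_bad("scales must be non-empty and positive")
  psi <- switch(mother, mexh = ricker,
                stop_bad("unknown mother wavelet: ", mother))
  n <- length(x)
  out <- matrix(0, nrow = length(scales), ncol = n)
  for (si in seq_along(scales)) {
    m <- scales[si]
    half <- ceiling(8 * m)   # mexh is < 1e-12 beyond 8 scale units
    k <- (-half):half
    kern <- psi(k / m) / sqrt(m)
    # correlation W(tau) = sum_t x[t] kern[t - tau]
    full <- stats::convolve(x, kern, type = "open")
    out[si, ] <- full[(half + 1):(half + n)]
  }
  out
}
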