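test_that("wavelet filters are orthonormal quadrature pairs", {
  for (w in c("haar", "db4", "db6")) {
    h <- wavelet_filter(w)
    expect_equal(sum(h), sqrt(2), tolerance = 1e-12)
    expect_equal(sum(h^2), 1, tolerance = 1e-12)
    # orthogonality to even shifts
    for (s in seq_len(length(h) / 2 - 1))
      expect_equal(sum(h * c(rep(0, 2 * s), h[seq_len(length(h) - 2 * s)])),
                   0, tolerance = 1e-12)
  }
  expect_error(wavelet_filter("db99"), "unknown wavelet")
})

test_that("periodized DWT reconstructs perfectly and preserves energy", {
  withr_seed <- 42
  set.seed(withr_seed)
  for (w in c("haar", "db4", "db6")) {
    x <- rnorm(256)
    cf <- dwt_periodic(x, w, levels = 5)
    expect_equal(idwt_periodic(cf), x, tolerance = 1e-10)
    # orthonormal transform preserves energy
    expect_equal(sum(cf$approx^2) + sum(unlist(cf$details)^2), sum(x^2),
                 tolerance = 1e-10)
  }
  expect_error(dwt_periodic(rnorm(100), "db4", 3), "divisible")
})

test_that("CWT matches direct-summation oracle and Eq-form behavior", {
  # impulse response: row equals the (time-reversed) scaled mother wavelet
  n <- 201
  x <- numeric(n); x[101] <- 1
  m <- 6
  W <- wavelet_transform(x, scales = m)
  psi <- function(t) (2 / (sqrt(3) * pi^0.25)) * (1 - t^2) * exp(-t^2 / 2)
  # direct summation oracle: W(tau) = sum_t x[t] psi((t - tau)/m) / sqrt(m)
  oracle <- vapply(seq_len(n), function(tau)
    sum(x * psi(((seq_len(n)) - tau) / m)) / sqrt(m), numeric(1))
  expect_lt(max(abs(as.numeric(W[1, ]) - oracle)), 1e-12)

  # zero signal -> zero coefficients (linearity)
  expect_true(all(wavelet_transform(numeric(128), scales = c(2, 4)) == 0))

  # sinusoid: |coefficients| maximal at the scale matching its period
  fs <- 100; t <- (0:999) / fs
  x <- sin(2 * pi * 5 * t)     # 5 Hz
  scales <- 1:30
  W <- wavelet_transform(x, scales)
  power <- rowMeans(abs(W[, 300:700])^2)
  best <- scales[which.max(power)]
  # mexican hat center frequency ~ fs/(2*pi*m/sqrt(2.5)); brute-force scan
  # says the peak scale for 5 Hz at fs 100 lies near 5; allow +/- 2
  expect_lt(abs(best - fs * sqrt(2.5) / (2 * pi * 5)), 2.5)
  expect_error(wavelet_transform(c(1, NA, 3), 2), "finite")
  expect_error(wavelet_transform(x, numeric(0)), "scales")
})

test_that("denoise removes baseline wander and preserves clean ECG", {
  clean <- synth_ecg(synth_ecg_config(n_beats = 20, noise_sd = 0,
                                      baseline_amp = 0, seed = 5))
  fs <- clean$signal$fs
  n <- length(clean$signal$samples)
  t <- (seq_len(n) - 1) / fs
  drift <- 0.5 * sin(2 * pi * 0.3 * t)
  noisy <- ecg_signal(clean$signal$samples + drift, fs)

  den <- denoise(noisy)
  band_power <- function(x, lo, hi) {
    sp <- Mod(fft(x))^2
    f <- (seq_along(x) - 1) * fs / length(x)
    sum(sp[f >= lo & f <= hi])
  }
  # sub-0.5 Hz power reduced by >= 90%
  expect_lt(band_power(den$samples, 0.01, 0.5),
            0.1 * band_power(noisy$samples, 0.01, 0.5))
  # denoising a clean signal preserves morphology
  expect_gt(cor(denoise(clean$signal)$samples, clean$signal$samples), 0.99)
  # and removing the drift still recovers the clean trace closely
  expect_gt(cor(den$samples, clean$signal$samples), 0.98)
  # zero in, zero out
  z <- denoise(ecg_signal(numeric(1024), fs))
  expect_true(all(z$samples == 0))
  # idempotence up to tolerance: second pass changes RMS by < 5%
  den2 <- denoise(den)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(den2$samples - den$samples), 0.05 * rms(den$samples))
  expect_error(denoise(ecg_signal(rnorm(100), 360)), "too short")
})

test_that("segment_beats cuts exact 235-sample windows and drops edges", {
  x <- ecg_signal(rnorm(1000), 360)
  ann <- data.frame(r_index = c(50L, 200L, 500L, 900L),
                    aami_class = c("N", "N", "V", "N"))
  bs <- segment_beats(x, ann)
  # r=50 lacks the 90-sample pre-window; r=900 lacks the 144 post-window
  expect_equal(nrow(bs$beats), 2)
  expect_equal(bs$dropped, 2)
  expect_equal(nrow(bs$beats) + bs$dropped, nrow(ann))
  expect_equal(ncol(bs$beats), 235)
  expect_equal(bs$r_offset, 90)
  # window [r-90, r+144] inclusive: for r=200, samples 110..344 (0-based)
  expect_equal(bs$beats[1, ], x$samples[(110:344) + 1])
  expect_equal(bs$beats[1, 91], x$samples[201])   # R at offset 90
  expect_equal(bs$labels, c("N", "V"))
})

test_that("beat invariants hold over random R placements", {
  set.seed(9)
  x <- ecg_signal(rnorm(5000), 360)
  r <- sort(sample(0:4999, 60))
  ann <- data.frame(r_index = r, aami_class = sample(c("N", "S", "V", "F"),
                                                     60, replace = TRUE))
  bs <- segment_beats(x, ann)
  expect_equal(nrow(bs$beats) + bs$dropped, 60)
  expect_true(all(bs$r_index - 90 >= 0))
  expect_true(all(bs$r_index + 144 <= 4999))
  for (i in seq_along(bs$r_index))
    expect_equal(bs$beats[i, 91], x$samples[bs$r_index[i] + 1])
})
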