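make_feature_fixture <- function(seed = 3) {
  rec <- mixed_record(n_beats = 30, seed = seed)
  den <- denoise(rec$signal)
  bs <- segment_beats(den, synth_annotations(rec$truth))
  fids <- delineate_record(den, bs$r_index)
  list(rec = rec, den = den, bs = bs, fids = fids,
       tab = extract_features(den, bs, fids))
}

test_that("interval features are index differences over fs", {
  fx <- make_feature_fixture()
  fs <- 360
  tab <- fx$tab
  # rr_inter matches the planted R spacing
  rr_truth <- diff(fx$bs$r_index) / fs
  expect_equal(tab$rr_inter[-1], rr_truth, tolerance = 1e-12)
  # first beat gets the record median RR
  expect_equal(tab$rr_inter[1], median(rr_truth), tolerance = 1e-12)
  # qrs_len recomputed from fiducials
  for (i in c(1, 10, 25)) {
    f <- fx$fids[[i]]
    expect_equal(tab$qrs_len[i], (f$qrs_off - f$qrs_on) / fs)
    expect_equal(tab$qt_inter[i], (f$t_off - f$qrs_on) / fs)
    expect_equal(tab$st_seg[i], (f$t_on - f$qrs_off) / fs)
  }
  # morph block is the raw beat matrix
  expect_equal(unname(as.matrix(tab[, sprintf("morph_%03d", 0:234)])),
               unname(fx$bs$beats))
})

test_that("amplitudes reflect the planted Gaussian construction", {
  rec <- synth_ecg(synth_ecg_config(n_beats = 10, noise_sd = 0,
                                    baseline_amp = 0, seed = 5))
  den <- denoise(rec$signal)
  bs <- segment_beats(den, synth_annotations(rec$truth))
  fids <- delineate_record(den, bs$r_index)
  tab <- extract_features(den, bs, fids)
  # planted N-beat R amplitude is 1.0 mV; baseline removal re-references
  # the trace to a zero isoelectric level, subtracting the beats' own DC
  # (~0.1 mV here), so amplitudes sit slightly below construction values
  expect_true(all(tab$r_amp > 0.8 & tab$r_amp < 1.02))
  expect_true(all(tab$t_amp > 0.2 & tab$t_amp < 0.37))
  expect_lt(diff(range(tab$r_amp)), 0.05)   # consistent across beats
})

test_that("imputation fills missing features with training medians", {
  fx <- make_feature_fixture()
  tab <- fx$tab
  tab$p_len[2] <- NA; tab$t_amp[5] <- NA
  imp <- impute_features(tab, train_rows = seq_len(nrow(tab)))
  expect_false(anyNA(imp$table[, c("p_len", "t_amp")]))
  expect_equal(imp$table$p_len[2],
               median(tab$p_len, na.rm = TRUE))
  expect_true(imp$flags[2, "p_len"])
  # external medians are honored
  med <- imp$medians; med["p_len"] <- 99
  imp2 <- impute_features(tab, medians = med)
  expect_equal(imp2$table$p_len[2], 99)
})

test_that("combine_features produces the documented column counts", {
  fx <- make_feature_fixture()
  imp <- impute_features(fx$tab)
  dims <- function(...) ncol(combine_features(imp$table,
                                              feature_selection(...)))
  expect_equal(dims(TRUE, FALSE, FALSE), 235)
  expect_equal(dims(FALSE, TRUE, FALSE), 7)
  expect_equal(dims(FALSE, FALSE, TRUE), 1)
  expect_equal(dims(TRUE, TRUE, FALSE), 242)
  expect_equal(dims(TRUE, FALSE, TRUE), 236)
  expect_equal(dims(FALSE, TRUE, TRUE), 8)
  expect_equal(dims(TRUE, TRUE, TRUE), 243)
  # order is Morph || Inter || Amp
  cn <- colnames(combine_features(imp$table, feature_selection()))
  expect_equal(cn[1], "morph_000")
  expect_equal(cn[236:243], c("p_len", "qrs_len", "t_len", "rr_inter",
                              "pr_inter", "st_seg", "qt_inter", "r_amp"))
  expect_error(feature_selection(FALSE, FALSE, FALSE), "at least one")
})

test_that("min-max normalizer scales to [0,1] on train, clips on apply", {
  expect_equal(apply_normalizer(fit_normalizer(cbind(c(0, 5, 10))),
                                cbind(c(0, 5, 10)))[, 1],
               c(0, 0.5, 1))
  # constant column maps to zero
  X <- cbind(a = c(2, 2, 2), b = c(1, 2, 3))
  out <- apply_normalizer(fit_normalizer(X), X)
  expect_true(all(out[, "a"] == 0))
  # train/apply on identical matrices stays in [0,1] (random property)
  set.seed(21)
  for (i in 1:10) {
    M <- matrix(rnorm(40), 8)
    out <- apply_normalizer(fit_normalizer(M), M)
    expect_true(all(out >= 0 & out <= 1))
  }
  # out-of-range test values clip to [-0.5, 1.5]
  norm <- fit_normalizer(cbind(c(0, 1)))
  expect_equal(apply_normalizer(norm, cbind(c(-10, 10)))[, 1], c(-0.5, 1.5))
  expect_error(apply_normalizer(list(), cbind(1)), "not a fitted")
})

test_that("normalization is invariant to affine rescaling after refit", {
  set.seed(31)
  M <- matrix(rnorm(60), 12)
  M2 <- M
  M2[, 2] <- 7 * M2[, 2] + 3
  out1 <- apply_normalizer(fit_normalizer(M), M)
  out2 <- apply_normalizer(fit_normalizer(M2), M2)
  expect_equal(out1, out2, tolerance = 1e-12)
})
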