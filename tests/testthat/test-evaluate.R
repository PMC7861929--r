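test_that("confusion_matrix counts true-by-predicted cells", {
  cm <- confusion_matrix(c("N", "S", "V", "F"), c("N", "S", "V", "F"))
  expect_equal(unname(diag(cm)), rep(1L, 4))
  expect_equal(sum(cm), 4L)
  cm0 <- confusion_matrix(character(0), character(0))
  expect_true(all(cm0 == 0))
  expect_error(confusion_matrix(c("N", "S"), "N"), "equal length")
  expect_error(confusion_matrix("Q", "N"), "outside")

  set.seed(6)
  y_true <- sample(c("N", "S", "V", "F"), 1000, replace = TRUE)
  y_pred <- sample(c("N", "S", "V", "F"), 1000, replace = TRUE)
  cm <- confusion_matrix(y_true, y_pred)
  expect_equal(unname(rowSums(cm)),
               as.numeric(table(factor(y_true, c("N", "S", "V", "F")))))
  expect_equal(sum(cm), 1000L)
})

test_that("class_counts partitions the matrix per class", {
  cm <- ref_confusion("morph")
  cc <- class_counts(cm, "N")
  expect_equal(cc, list(tp = 9009, fn = 26, fp = 75, tn = 1031))
  # per-class partition sums to grand total; tp+fn = row sum, tp+fp = col sum
  for (cls in c("N", "S", "V", "F")) {
    cc <- class_counts(cm, cls)
    expect_equal(cc$tp + cc$fn + cc$fp + cc$tn, sum(cm))
    i <- match(cls, c("N", "S", "V", "F"))
    expect_equal(cc$tp + cc$fn, sum(cm[i, ]))
    expect_equal(cc$tp + cc$fp, sum(cm[, i]))
  }
  # diagonal matrix: no errors
  cc <- class_counts(diag(c(5, 6, 7, 8)), "S")
  expect_equal(cc$fn + cc$fp, 0)
  # single-beat matrix partitions to 1
  m1 <- matrix(0, 4, 4); m1[2, 3] <- 1
  cc <- class_counts(m1, "V")
  expect_equal(cc$tp + cc$fn + cc$fp + cc$tn, 1)
})

test_that("reference confusion matrices reproduce the per-class tables", {
  ref <- ref_metric_blocks()
  for (block in unique(ref$block)) {
    cm <- ref_confusion(block)
    rep <- classification_report(cm)
    want <- ref[ref$block == block, ]
    got <- merge(rep, want, by = "class", suffixes = c("_got", "_want"))
    expect_equal(got$se_got, got$se_want, tolerance = 1e-9,
                 info = paste(block, "se"))
    expect_equal(got$sp_got, got$sp_want, tolerance = 1e-9,
                 info = paste(block, "sp"))
    expect_equal(got$ppv_got, got$ppv_want, tolerance = 1e-9,
                 info = paste(block, "ppv"))
    expect_equal(got$acc_got, got$acc_want, tolerance = 1e-9,
                 info = paste(block, "acc"))
  }
})

test_that("overall accuracy matches the published block accuracies", {
  want <- read.csv(ref_path("ref_overall.csv"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(want)))
    expect_equal(round_half_up(overall_accuracy(ref_confusion(want$block[i]))),
                 want$accuracy[i], info = want$block[i])
  expect_equal(overall_accuracy(diag(c(1, 1, 1, 1))), 100)
  expect_error(overall_accuracy(matrix(0, 4, 4)), "empty")
})

test_that("class_metrics handles degenerate counts", {
  expect_error(class_metrics(list(tp = 0, fn = 0, fp = 3, tn = 7)),
               "no true members")
  m <- class_metrics(list(tp = 0, fn = 5, fp = 0, tn = 5))
  expect_true(is.na(m$ppv))
  expect_equal(m$se, 0)
})

test_that("reports are deterministic and CSV round-trips preserve counts", {
  cm <- ref_confusion("morph_inter_amp")
  r1 <- classification_report(cm)
  r2 <- classification_report(cm)
  expect_identical(r1, r2)
  expect_equal(attr(r1, "overall_accuracy"), 98.91)
  p <- file.path(tempdir(), "cm.csv")
  write_confusion_csv(cm, p)
  expect_equal(unclass(read_confusion_csv(p)), unclass(as.matrix(cm)),
               ignore_attr = TRUE)
  expect_error(classification_report(matrix(0, 4, 4)), "empty")
})

test_that("rounding is half-up to two decimals", {
  expect_equal(round_half_up(99.005), 99.01)
  expect_equal(round_half_up(1.925), 1.93)
  expect_equal(round_half_up(-1.925), -1.93)
  expect_equal(round_half_up(73.0769230769), 73.08)
})
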