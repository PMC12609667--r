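# Confusion-matrix metrics and bootstrap machinery.

# Published aggregate confusion-matrix counts used as a fixed arithmetic
# fixture (foreground = nanowire).
TP <- 19502345; FN <- 1636842; FP <- 5798124; TN <- 51705679

test_that("accumulation counts pixels correctly and commutes", {
  cm <- cm_accumulate(rep(1L, 100), rep(1L, 100))
  expect_equal(unclass(cm), matrix(c(0, 0, 0, 100), 2, 2), ignore_attr = TRUE)
  # four-pixel enumeration
  cm2 <- cm_accumulate(c(0L, 1L, 1L, 1L), c(0L, 0L, 1L, 1L))
  expect_equal(unclass(cm2), matrix(c(1, 0, 1, 2), 2, 2), ignore_attr = TRUE)
  # order independence
  a <- list(pred = c(0L, 1L), ref = c(1L, 1L))
  b <- list(pred = c(1L, 0L, 0L), ref = c(0L, 0L, 1L))
  ab <- cm_accumulate(b$pred, b$ref, cm_accumulate(a$pred, a$ref))
  ba <- cm_accumulate(a$pred, a$ref, cm_accumulate(b$pred, b$ref))
  expect_equal(ab, ba)
  expect_error(cm_accumulate(c(0L, 1L), c(0L, 1L, 0L)), "disagree")
})

test_that("mIoU closed forms and zero-union handling", {
  perfect <- confusion_from_counts(tp = 50, fn = 0, fp = 0, tn = 50)
  expect_equal(miou(perfect), 1.0)
  cm <- cm_accumulate(c(0L, 1L, 1L, 1L), c(0L, 0L, 1L, 1L))
  expect_equal(miou(cm), 0.5 * (1 / 2 + 2 / 3))
  # absent class is excluded from the mean with a warning
  cm3 <- matrix(0, 3, 3)
  cm3[1, 1] <- 5; cm3[2, 2] <- 5
  expect_warning(m <- miou(structure(cm3, class = c("wbs_confusion",
                                                    "matrix", "array"))),
                 "zero union")
  expect_equal(m, 1.0)
})

test_that("published-matrix metrics equal long-hand arithmetic", {
  cm <- confusion_from_counts(TP, FN, FP, TN)
  total <- TP + FN + FP + TN
  # long-hand oracle, written out from the definitions
  acc_hand <- (TP + TN) / total
  iou_fg <- TP / (TP + FP + FN)
  iou_bg <- TN / (TN + FP + FN)
  p <- TP / (TP + FP); r <- TP / (TP + FN)
  f1_hand <- 2 * p * r / (p + r)
  po <- acc_hand
  pe <- ((TP + FN) * (TP + FP) + (TN + FP) * (TN + FN)) / total^2
  kappa_hand <- (po - pe) / (1 - pe)
  expect_equal(accuracy(cm), acc_hand, tolerance = 1e-12)
  expect_equal(miou(cm), (iou_fg + iou_bg) / 2, tolerance = 1e-12)
  expect_equal(f1_score(cm), f1_hand, tolerance = 1e-12)
  expect_equal(as.numeric(kappa(cm)), kappa_hand, tolerance = 1e-12)
  # the matrix does NOT reproduce the published headline table: the
  # divergence is asserted, not reconciled
  expect_gt(abs(accuracy(cm) - 0.8995), 0.004)
  expect_gt(abs(miou(cm) - 0.7759), 0.02)
  expect_gt(abs(f1_score(cm) - 0.8722), 0.03)
})

test_that("F1 fixed point and degenerate denominators", {
  # P = R implies F1 = P
  cm <- confusion_from_counts(tp = 30, fn = 10, fp = 10, tn = 50)
  prf <- precision_recall_f1(cm)
  expect_equal(prf$precision, prf$recall)
  expect_equal(prf$f1, prf$precision)
  # empty prediction and reference foreground: flagged zero
  cm0 <- confusion_from_counts(tp = 0, fn = 0, fp = 0, tn = 10)
  prf0 <- precision_recall_f1(cm0)
  expect_equal(prf0$f1, 0)
  expect_true(attr(prf0, "degenerate"))
})

test_that("kappa closed forms: perfect agreement and pure chance", {
  expect_equal(as.numeric(kappa(confusion_from_counts(50, 0, 0, 50))), 1.0)
  # rows proportional to the column margins: po = pe, kappa = 0
  cm <- structure(outer(c(30, 70), c(40, 60)) / 100,
                  class = c("wbs_confusion", "matrix", "array"))
  expect_equal(as.numeric(kappa(cm)), 0, tolerance = 1e-12)
  # single-class degenerate case is flagged
  k <- kappa(confusion_from_counts(0, 0, 0, 10))
  expect_equal(as.numeric(k), 0)
  expect_true(attr(k, "degenerate"))
})

test_that("all metrics match naive per-pixel counting on random masks", {
  set.seed(123)
  for (rep in 1:100) {
    pred <- matrix(sample(0:1, 256, TRUE), 16, 16)
    ref <- matrix(sample(0:1, 256, TRUE, prob = c(0.8, 0.2)), 16, 16)
    if (sum(ref) == 0 || sum(pred) == 0) next
    cm <- cm_accumulate(pred, ref)
    o <- oracle_metrics(pred, ref)
    expect_identical(miou(cm), o$miou)
    expect_identical(accuracy(cm), o$accuracy)
    expect_identical(f1_score(cm), o$f1)
    expect_identical(as.numeric(kappa(cm)), o$kappa)
  }
})

test_that("metrics are invariant to simultaneous class relabeling", {
  set.seed(5)
  pred <- matrix(sample(0:1, 64, TRUE), 8, 8)
  ref <- matrix(sample(0:1, 64, TRUE), 8, 8)
  cm <- cm_accumulate(pred, ref)
  cms <- cm_accumulate(1L - pred, 1L - ref)
  expect_equal(accuracy(cm), accuracy(cms))
  expect_equal(as.numeric(kappa(cm)), as.numeric(kappa(cms)))
  expect_equal(per_class_iou(cm), rev(per_class_iou(cms)))
})

test_that("bootstrap endpoints for identical and shifted score lists", {
  a <- c(0.5, 0.6, 0.7, 0.8)
  bs <- bootstrap_compare(a, a, n_resamples = 500L, seed = 3L)
  expect_equal(bs$diff_ci, c(0, 0))
  expect_false(bs$significant)
  bs2 <- bootstrap_compare(a, a + 2.0, n_resamples = 500L, seed = 3L)
  expect_equal(bs2$diff_ci, c(2, 2), tolerance = 1e-12)
  expect_true(bs2$significant)
  expect_error(bootstrap_compare(numeric(0), numeric(0)), "non-empty")
})

test_that("bootstrap brackets a known shift in noisy paired scores", {
  set.seed(17)
  a <- rnorm(50, 5, 0.5)
  b <- a + 1.5 + rnorm(50, 0, 0.5)
  bs <- bootstrap_compare(a, b, n_resamples = 10000L, seed = 7L)
  expect_equal(bs$n_resamples, 10000L)
  expect_length(bs$diffs, 10000L)
  expect_lt(bs$diff_ci[1], 1.5)
  expect_gt(bs$diff_ci[2], 1.5)
  expect_gt(bs$diff_ci[1], 0)
  expect_true(bs$significant)
  # seeded run is exactly reproducible
  bs2 <- bootstrap_compare(a, b, n_resamples = 10000L, seed = 7L)
  expect_identical(bs$diff_ci, bs2$diff_ci)
})

test_that("bootstrap interval coverage of a known shift is near nominal", {
  set.seed(31)
  hits <- 0L
  for (rep in 1:100) {
    a <- rnorm(200, 10, 1)
    b <- a + 0.8 + rnorm(200, 0, 1)
    bs <- bootstrap_compare(a, b, n_resamples = 1000L, seed = rep)
    if (bs$diff_ci[1] <= 0.8 && 0.8 <= bs$diff_ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})
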