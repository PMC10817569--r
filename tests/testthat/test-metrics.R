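test_that("mcc matches hand-worked confusion matrices", {
  perfect <- confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(mcc(perfect), 1)
  cc <- structure(list(TP = 4, FP = 1, TN = 3, FN = 2),
                  class = "confusion_counts")
  expect_equal(mcc(cc), 10 / sqrt(600), tolerance = 1e-12)
  one_class <- confusion_counts(c(1, 0, 1), c(1, 1, 1))
  expect_equal(mcc(one_class), 0)
  expect_error(mcc(confusion_counts(numeric(0), numeric(0))), "empty")
})

test_that("f1 matches hand-worked confusion matrices", {
  cc <- structure(list(TP = 4, FP = 1, TN = 3, FN = 2),
                  class = "confusion_counts")
  expect_equal(f1(cc), 2 * 0.8 * (2 / 3) / (0.8 + 2 / 3), tolerance = 1e-12)
  perfect <- confusion_counts(c(1, 0), c(1, 0))
  expect_equal(f1(perfect), 1)
  no_tp <- confusion_counts(c(1, 1, 0), c(0, 0, 0))
  expect_equal(f1(no_tp), 0)
})

test_that("auc matches the pairwise-concordance definition", {
  scores <- c(0.9, 0.4, 0.8, 0.2, 0.1)
  labels <- c(1, 1, 0, 0, 0)
  expect_equal(auc(scores, labels), 5 / 6, tolerance = 1e-12)
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.5, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_error(auc(c(0.1, 0.9), c(1, 1)), "both outcome classes")
})

test_that("auc is invariant under strictly monotone score transforms", {
  set.seed(3)
  for (i in 1:30) {
    n <- sample(6:30, 1)
    s <- runif(n)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    base <- auc(s, y)
    expect_equal(auc(qlogis(s / 1.0001 + 1e-5), y), base, tolerance = 1e-12)
    expect_equal(auc(s^3, y), base, tolerance = 1e-12)
    expect_equal(auc(100 * s - 7, y), base, tolerance = 1e-12)
  }
})

test_that("metric implementations match brute-force oracles on random instances", {
  set.seed(99)
  for (i in 1:250) {
    n <- sample(2:30, 1)
    y <- c(0, 1, rbinom(max(n - 2, 0), 1, runif(1, 0.2, 0.8)))
    pred <- rbinom(length(y), 1, 0.5)
    cc <- confusion_counts(y, pred)
    expect_equal(mcc(cc), oracle_mcc(cc$TP, cc$FP, cc$TN, cc$FN),
                 tolerance = 1e-12)
    expect_equal(f1(cc), oracle_f1(cc$TP, cc$FP, cc$TN, cc$FN),
                 tolerance = 1e-12)
    s <- round(runif(length(y)), 2)  # rounding forces ties
    expect_equal(auc(s, y), oracle_auc(s, y), tolerance = 1e-12)
    nb <- sample(1:12, 1)
    expect_equal(ece(s, y, nb)$ece, oracle_ece(s, y, nb), tolerance = 1e-12)
  }
})

test_that("auc agrees with pROC's trapezoidal computation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:20) {
    y <- c(0, 1, rbinom(28, 1, 0.3))
    s <- runif(30)
    ref <- suppressMessages(pROC::auc(pROC::roc(
      y, s, quiet = TRUE, direction = "<", levels = c(0, 1)
    )))
    expect_equal(auc(s, y), as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("ece reproduces worked examples and degenerate reductions", {
  expect_equal(ece(rep(1, 5), rep(1, 5), 10)$ece, 0)
  # two bins: 0.5*|0.5-0.9| + 0.5*|0.0-0.1|
  rep2 <- ece(c(0.9, 0.9, 0.1, 0.1), c(1, 0, 0, 0), 2)
  expect_equal(rep2$ece, 0.25, tolerance = 1e-12)
  expect_equal(rep2$bins$count, c(2L, 2L))
  # single bin reduces to |event rate - mean probability|
  set.seed(4)
  p <- runif(40)
  y <- rbinom(40, 1, 0.4)
  expect_equal(ece(p, y, 1)$ece, abs(mean(y) - mean(p)), tolerance = 1e-12)
  # bin counts always sum to n, ECE within [0,1]
  rep10 <- ece(p, y, 10)
  expect_equal(sum(rep10$bins$count), 40L)
  expect_true(rep10$ece >= 0 && rep10$ece <= 1)
})

test_that("the predicted-class ECE variant uses class confidence", {
  # all predictions confident and correct: class-variant ECE is small
  p <- c(0.95, 0.9, 0.05, 0.1)
  y <- c(1, 1, 0, 0)
  cls <- ece(p, y, 10, variant = "class")
  expect_equal(cls$ece, mean(abs(c(0.95, 0.9, 0.95, 0.9) - 1)),
               tolerance = 1e-12)
})

test_that("paired_t_test matches stats::t.test and flags degenerate input", {
  a <- c(1, 2, 3, 4)
  b <- c(0, 0, 1, 1)
  got <- paired_t_test(a, b)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(got$t, mean(a - b) / (sd(a - b) / 2), tolerance = 1e-12)
  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$zero_variance)
  shift <- paired_t_test(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_true(shift$zero_variance)
  expect_equal(shift$p_value, 0)
  expect_error(paired_t_test(1, 1), "at least 2")
})

test_that("averaged_roc interpolates onto the FPR grid correctly", {
  # single perfect iteration passes through (0, 1)
  perfect <- averaged_roc(list(c(0.9, 0.8, 0.2, 0.1)), list(c(1, 1, 0, 0)))
  expect_equal(perfect$tpr_mean[perfect$fpr == 0], 1)
  expect_equal(nrow(perfect), 101)
  # identical iterations have zero dispersion
  s <- runif(30)
  y <- c(0, 1, rbinom(28, 1, 0.4))
  two <- averaged_roc(list(s, s), list(y, y))
  expect_true(all(two$tpr_sd == 0))
  # trapezoidal area of the interpolated curve approximates the AUC
  scores <- c(0.9, 0.4, 0.8, 0.2, 0.1)
  labels <- c(1, 1, 0, 0, 0)
  curve <- averaged_roc(list(scores), list(labels))
  area <- sum(diff(curve$fpr) * (head(curve$tpr_mean, -1) +
                                   tail(curve$tpr_mean, -1)) / 2)
  expect_equal(area, 5 / 6, tolerance = 0.01)
})
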