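# Confusion-matrix metrics, macro aggregation, ROC-AUC and paired tests.

test_that("confusion matrices count (true, pred) pairs exactly", {
  y <- c(0, 1, 2, 2, 1, 0, 2)
  cm <- confusion_matrix(y, y, 3)
  expect_equal(diag(cm), c(`0` = 2L, `1` = 2L, `2` = 3L))
  expect_equal(sum(cm), length(y))
  set.seed(3)
  yt <- sample(0:2, 60, TRUE); yp <- sample(0:2, 60, TRUE)
  cm2 <- confusion_matrix(yt, yp, 3)
  # brute-force pair counting oracle
  for (i in 0:2) for (j in 0:2)
    expect_equal(cm2[i + 1, j + 1], sum(yt == i & yp == j))
  expect_equal(sum(cm2), 60)
  expect_error(confusion_matrix(c(0, 3), c(0, 1), 3), "range")
})

test_that("per-class metrics reproduce published recall percentages from narrative counts", {
  hc <- hybrid_counts()
  cm <- cm_from_counts(hc$correct, hc$total)
  m <- class_metrics(cm)
  expect_equal(round(m$class_accuracy[m$class == "NV"], 1), 99.7)
  expect_equal(round(m$class_accuracy[m$class == "MEL"], 1), 93.7)
  expect_equal(round(m$class_accuracy[m$class == "AKIEC"], 1), 87.7)
  expect_equal(round(m$class_accuracy[m$class == "BCC"], 1), 92.2)
  expect_equal(round(m$sensitivity[m$class == "NV"], 1), 99.7)  # same quantity
  ec <- vit_counts()
  me <- class_metrics(cm_from_counts(ec$correct, ec$total))
  expect_equal(round(me$class_accuracy[me$class == "NV"], 1), 98.2)
  expect_equal(round(me$class_accuracy[me$class == "BKL"], 1), 94.1)
  expect_equal(round(me$class_accuracy[me$class == "DF"], 1), 30.4)
  dn <- densenet_nv_counts()
  expect_equal(round(dn$correct / dn$total * 100, 1), 97.0)
})

test_that("one-vs-rest bookkeeping identities hold and perfect predictions score 100", {
  set.seed(9)
  yt <- sample(0:3, 80, TRUE); yp <- sample(0:3, 80, TRUE)
  cm <- confusion_matrix(yt, yp, 4)
  m <- class_metrics(cm)
  expect_equal(m$tp + m$fp + m$fn + m$tn, rep(80, 4))         # per-class total
  expect_equal(sum(m$tp), sum(diag(cm)))                      # trace identity
  # duplicating every sample leaves all rates unchanged
  m2 <- class_metrics(confusion_matrix(rep(yt, 2), rep(yp, 2), 4))
  expect_equal(m2$sensitivity, m$sensitivity)
  expect_equal(m2$specificity, m$specificity)
  expect_equal(m2$precision, m$precision)
  # perfect diagonal
  mp <- class_metrics(diag(c(5, 3, 9)))
  expect_equal(mp$precision, rep(100, 3))
  expect_equal(mp$sensitivity, rep(100, 3))
  expect_equal(mp$specificity, rep(100, 3))
  expect_equal(mp$class_accuracy, rep(100, 3))
  # zero denominators give NaN, not errors
  mz <- class_metrics(matrix(c(2, 0, 0, 0), 2, 2))
  expect_true(is.nan(mz$sensitivity[2]))
})

test_that("macro means reproduce the published Overall rows", {
  t3 <- densenet_table3()
  expect_equal(macro_overall(t3$sensitivity), 66.29)
  expect_equal(macro_overall(t3$precision), 75.00)
  expect_equal(macro_overall(t3$auc), 76.03)
  t5 <- hybrid_table5()
  expect_equal(macro_overall(t5$sensitivity), 90.80)
  expect_equal(macro_overall(rep(42.5, 7)), 42.5)
  expect_error(macro_overall(numeric(0)), "class")
})

test_that("ROC-AUC equals the brute-force pairwise probability with half ties", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(1, 2, 3, 4)), 1)          # separated
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)          # all ties
  set.seed(21)
  for (r in 1:20) {
    n <- sample(10:200, 1)
    lab <- rbinom(n, 1, 0.4)
    if (length(unique(lab)) < 2) next
    sc <- round(rnorm(n), 1)   # coarse scores force ties
    pos <- sc[lab == 1]; neg <- sc[lab == 0]
    brute <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(roc_auc(lab, sc), brute, tolerance = 1e-12)
  }
  expect_error(roc_auc(rep(1, 5), rnorm(5)), "present")
})

test_that("ROC-AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  lab <- rbinom(100, 1, 0.5); sc <- rnorm(100) + lab
  expect_equal(roc_auc(lab, sc),
               as.numeric(suppressMessages(pROC::auc(lab, sc, direction = "<"))),
               tolerance = 1e-12)
})

test_that("McNemar's test matches its closed forms", {
  # symmetric discordance: zero statistic, p = 1
  m0 <- mcnemar_test(5, 5, method = "chisq")
  expect_equal(m0$statistic, 0)
  expect_equal(m0$p_value, 1)
  # corrected chi-squared worked example
  m1 <- mcnemar_test(15, 5, method = "chisq")
  expect_equal(m1$statistic, 81 / 20)
  expect_equal(m1$p_value, pchisq(4.05, 1, lower.tail = FALSE))
  expect_equal(m1$p_value, 0.0442, tolerance = 1e-3)
  # agreement with the standard library implementation
  tab <- matrix(c(30, 5, 15, 40), 2, 2)
  expect_equal(mcnemar_test(15, 5, method = "chisq")$p_value,
               stats::mcnemar.test(tab)$p.value, tolerance = 1e-12)
  # exact binomial variant for small discordance
  expect_equal(mcnemar_test(1, 0)$p_value, 1)
  expect_equal(mcnemar_test(9, 1)$p_value,
               min(1, 2 * pbinom(1, 10, 0.5)), tolerance = 1e-12)
  expect_error(mcnemar_test(0, 0), "discordant")
  # construction from paired correctness vectors
  pp <- paired_predictions(c(TRUE, TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(pp$b, 2); expect_equal(pp$c, 1)
})

test_that("prediction-table evaluation assembles matrix, per-class and overall blocks", {
  set.seed(5)
  n <- 140
  yt <- sample(0:6, n, TRUE)
  sc <- matrix(runif(n * 7), n, 7)
  sc[cbind(1:n, yt + 1)] <- sc[cbind(1:n, yt + 1)] + 0.8   # informative scores
  yp <- max.col(sc) - 1L
  preds <- data.frame(true_label = yt, pred_label = yp)
  preds[paste0("score_", 0:6)] <- sc
  ev <- evaluate_predictions(preds)
  expect_equal(sum(ev$confusion), n)
  expect_equal(nrow(ev$per_class), 7)
  expect_true(all(ev$per_class$auc > 50))
  expect_equal(ev$overall$micro_accuracy, mean(yt == yp) * 100)
  # micro accuracy from the matrix agrees with direct computation
  expect_equal(micro_accuracy(ev$confusion), mean(yt == yp) * 100)
})

test_that("the literal TPR/FPR ratio is exposed separately from ROC-AUC", {
  expect_equal(tpr_fpr_ratio(tp = 80, fp = 10, fn = 20, tn = 90), 0.8 / 0.1)
  expect_equal(tpr_fpr_ratio(tp = 5, fp = 0, fn = 5, tn = 10), Inf)
  tpt <- two_proportion_test(90, 100, 70, 100)
  expect_lt(tpt$p_value, 0.01)
  expect_equal(tpt$p1, 0.9)
})
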