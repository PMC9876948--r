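# Confusion matrices, summary metrics, ROC/AUC and correlation.

test_that("confusion_matrix cross-tabulates correctly", {
  cm <- confusion_matrix(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_identical(unclass(cm), list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))

  perfect <- confusion_matrix(c(1, 1, 1, 0, 0), c(1, 1, 1, 0, 0))
  expect_identical(perfect$fp, 0L)
  expect_identical(perfect$fn, 0L)

  histo <- confusion_matrix(
    c(TRUE, TRUE, FALSE, TRUE),
    c("acute_inflamed", "gangrenous", "perforated", "negative"))
  expect_identical(histo$tp, 2L)
  expect_identical(histo$fn, 1L)
  expect_identical(histo$fp, 1L)

  expect_error(confusion_matrix(c(1, 0), c(1)), "equal length")
  expect_error(confusion_matrix(logical(0), logical(0)), "empty")
})

test_that("confusion_matrix is invariant to patient order", {
  set.seed(3)
  calls <- runif(50) < 0.5
  labels <- runif(50) < 0.7
  perm <- sample(50)
  expect_identical(unclass(confusion_matrix(calls, labels)),
                   unclass(confusion_matrix(calls[perm], labels[perm])))
})

test_that("metrics reproduce hand-checked rows from integer matrices", {
  alv <- round_metrics(diagnostic_metrics(new_confusion_matrix(107, 4, 14, 7)))
  expect_equal(alv[["sensitivity"]], 88.4)
  expect_equal(alv[["specificity"]], 63.6)
  expect_equal(alv[["ppv"]], 96.4)
  expect_equal(alv[["npv"]], 33.3)
  expect_equal(alv[["plr"]], 2.43)
  expect_equal(alv[["nlr"]], 0.18)
  expect_equal(alv[["accuracy"]], 86.4)  # 114/132 = 86.36%

  air <- diagnostic_metrics(new_confusion_matrix(94, 2, 27, 9))
  air_r <- round_metrics(air)
  expect_equal(air_r[["ppv"]], 97.9)
  expect_equal(air_r[["npv"]], 25.0)
  expect_equal(air_r[["plr"]], 4.27)
  expect_equal(air_r[["nlr"]], 0.27)
  expect_equal(round_half_up(air$accuracy, 2), 78.03)
})

test_that("a perfect classifier yields 100s, zero NLR and undefined PLR", {
  met <- diagnostic_metrics(new_confusion_matrix(8, 0, 0, 5))
  for (f in c("sensitivity", "specificity", "npv", "ppv", "accuracy")) {
    expect_equal(met[[f]], 100)
  }
  expect_equal(met$nlr, 0)
  expect_true(is.na(met$plr))
  expect_true("plr" %in% attr(met, "undefined"))
  expect_error(diagnostic_metrics(new_confusion_matrix(5, 0, 3, 0)),
               "both disease classes")
})

test_that("PPV obeys the Bayes identity and PLR >= 1 when sens+spec > 1", {
  set.seed(21)
  for (i in 1:200) {
    cm <- new_confusion_matrix(sample(0:60, 1), sample(0:20, 1),
                               sample(0:60, 1), sample(0:20, 1))
    if (cm$tp + cm$fn == 0 || cm$fp + cm$tn == 0) next
    met <- diagnostic_metrics(cm)
    sens <- met$sensitivity / 100; spec <- met$specificity / 100
    prev <- (cm$tp + cm$fn) / met$n
    if (!is.na(met$ppv)) {
      bayes <- 100 * sens * prev / (sens * prev + (1 - spec) * (1 - prev))
      expect_equal(met$ppv, bayes, tolerance = 1e-12)
    }
    if (!is.na(met$plr) && sens + spec > 1) {
      expect_gte(met$plr, 1)
    }
  }
})

test_that("AUC separates, is 0.5 under independence, and matches the pair-count oracle", {
  sep <- roc_auc(c(5, 6, 7, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  expect_equal(sep$auc, 1.0)

  set.seed(9)
  n <- 4000
  scores <- rnorm(n)
  labels <- runif(n) < 0.5
  n1 <- sum(labels); n0 <- n - n1
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(roc_auc(scores, labels)$auc - 0.5), 3 * se)

  # exhaustive pair-count equality on small instances with heavy ties
  set.seed(13)
  for (i in 1:60) {
    n <- sample(2:12, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)  # both classes guaranteed
    scores <- sample(1:4, n, replace = TRUE)
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels))
  }
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(31)
  scores <- sample(0:10, 80, replace = TRUE)
  labels <- c(TRUE, FALSE, runif(78) < 0.6)
  base <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, base)
  expect_equal(roc_auc(2 * scores + 3, labels)$auc, base)
  expect_equal(roc_auc(rank(scores, ties.method = "min"), labels)$auc, base)
})

test_that("AUC agrees with pROC on a random instance", {
  set.seed(5)
  scores <- sample(0:12, 200, replace = TRUE)
  labels <- runif(200) < 0.6
  ours <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref)
})

test_that("auc_difference composes roc_auc and is reproducible under a seed", {
  set.seed(17)
  labels <- c(TRUE, FALSE, runif(98) < 0.7)
  a <- rnorm(100) + labels
  b <- rnorm(100) + 1.5 * labels

  expect_equal(auc_difference(a, a, labels)$delta, 0)
  d <- auc_difference(a, b, labels)
  expect_equal(d$delta, roc_auc(b, labels)$auc - roc_auc(a, labels)$auc)

  b1 <- auc_difference(a, b, labels, boot_reps = 200, seed = 99)
  b2 <- auc_difference(a, b, labels, boot_reps = 200, seed = 99)
  expect_identical(b1$ci, b2$ci)
  expect_length(b1$ci, 2)
  expect_lte(b1$ci[1], b1$ci[2])
})

test_that("pearson_r closed-form cases and degenerate inputs", {
  x <- c(0.5, 1, 2, 4, 9)
  expect_equal(pearson_r(x, 2 * x + 1), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(c(1, 2), c(1, 2)), "at least 3")
})
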