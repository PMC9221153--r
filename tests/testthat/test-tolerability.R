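test_that("group tolerability is the mean of per-mouse category sums", {
  expect_equal(aggregateTolerability(rbind(rep(4, 5)))$group_mean, 20)
  expect_equal(aggregateTolerability(rbind(rep(0, 5)))$group_mean, 0)
  two <- aggregateTolerability(rbind(c(1, 0, 2, 0, 0), c(0, 0, 1, 0, 0)))
  expect_equal(two$group_mean, 2.0)
  expect_equal(two$totals, c(3, 1))
  expect_error(aggregateTolerability(rbind(c(5, 0, 0, 0, 0))), "\\[0, 4\\]")
  expect_error(aggregateTolerability(rbind(c(0.5, 0, 0, 0, 0))), "integers")
  expect_error(aggregateTolerability(rbind(c(1, 2, 3))), "5 category")
})

test_that("severity bins partition [0,20] at thresholds 4, 7 and 18", {
  expect_equal(as.character(classifySeverity(c(0.2, 13, 20, 3.9, 4, 7, 18, 18.1))),
               c("mild", "marked", "severe", "mild", "moderate", "marked",
                 "marked", "severe"))
  expect_error(classifySeverity(21), "\\[0, 20\\]")
  # monotone: higher score never maps to a less severe class
  s <- seq(0, 20, by = 0.25)
  expect_true(all(diff(as.integer(classifySeverity(s))) >= 0))
})

test_that("binary acceptability follows the at-or-below-4 rule", {
  expect_equal(as.character(binaryLabel(c(4, 4.5, 0, 20))),
               c("acceptable", "toxic", "acceptable", "toxic"))
})

test_that("AUC equals the exhaustive pair-counting oracle", {
  # perfectly separated and constant predictors first
  lab <- binaryLabel(c(0, 1, 9, 12))
  expect_equal(rocCurve(c(90, 80, 20, 10), lab)$auc, 1)
  expect_equal(rocCurve(rep(5, 4), lab)$auc, 0.5)
  expect_error(rocCurve(1:3, binaryLabel(c(0, 1, 2))), "both classes")

  withr::with_seed(91, {
    for (i in 1:100) {
      n <- sample(5:30, 1)
      predictor <- sample(0:20, n, replace = TRUE)  # ties likely
      toxic <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (!any(toxic) || all(toxic)) next
      expect_equal(rocCurve(predictor, toxic)$auc,
                   oracleAuc(predictor, toxic), tolerance = 1e-12)
    }
  })
})

test_that("flipping the predictor mirrors the AUC around one half", {
  withr::with_seed(92, {
    for (i in 1:20) {
      n <- sample(8:40, 1)
      predictor <- rnorm(n)
      toxic <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (!any(toxic) || all(toxic)) next
      expect_equal(rocCurve(predictor, toxic)$auc +
                     rocCurve(-predictor, toxic)$auc, 1,
                   tolerance = 1e-12)
    }
  })
})

test_that("ROC points run from (0,0) to (1,1) and are monotone", {
  withr::with_seed(93, {
    predictor <- rnorm(40, 70, 20)
    toxic <- predictor + rnorm(40, 0, 15) < 70
  })
  roc <- rocCurve(predictor, toxic)
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(roc$points$tpr[1], 0)
  expect_equal(roc$points$fpr[nrow(roc$points)], 1)
  expect_equal(roc$points$tpr[nrow(roc$points)], 1)
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
})

test_that("accuracy-vs-cutoff locates the plateau and reports its midpoint", {
  # predictor identical to the labels mapped to {0,1}: cutoff 0.5 is perfect
  toxic <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  predictor <- ifelse(toxic, 0, 1)
  res <- accuracyVsCutoff(predictor, toxic, grid = 0.5)
  expect_equal(res$best_accuracy, 1)

  # all-acceptable predictions at a cutoff below every score
  res2 <- accuracyVsCutoff(c(10, 20, 30, 40), c(TRUE, TRUE, FALSE, FALSE),
                           grid = -1)
  expect_equal(res2$curve$accuracy, 0.5)  # class prevalence

  # a separated instance has a plateau; its midpoint maximizes accuracy
  withr::with_seed(94, {
    sc <- c(rnorm(30, 40, 10), rnorm(30, 110, 10))
    toxic <- rep(c(TRUE, FALSE), each = 30)
  })
  res3 <- accuracyVsCutoff(sc, toxic)
  expect_equal(res3$best_accuracy, 1)
  atBest <- res3$curve$cutoff[res3$curve$accuracy == res3$best_accuracy]
  expect_equal(res3$best_cutoff, mean(range(atBest)))
  # accuracy at the optimum dominates the whole grid
  expect_true(all(res3$curve$accuracy <= res3$best_accuracy))
})

test_that("classification reports recompute exactly from their counts", {
  # hand-built instance: TP=3, FP=1, TN=5, FN=1 at cutoff 70
  predictor <- c(60, 65, 68, 69, 80, 85, 90, 95, 99, 75)
  toxic <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
             FALSE, TRUE)
  rep1 <- classificationReport(predictor, toxic, cutoff = 70)
  expect_equal(c(rep1@tp, rep1@fp, rep1@tn, rep1@fn), c(3L, 1L, 5L, 1L))
  expect_equal(rep1@accuracy, 0.8)
  expect_equal(rep1@npv, 5 / 6)
  expect_equal(rep1@ppv, 3 / 4)
  expect_equal(rep1@sensitivity, 3 / 4)
  expect_equal(rep1@specificity, 5 / 6)
  # metrics consistent with counts by reconstruction
  expect_equal(rep1@accuracy,
               (rep1@tp + rep1@tn) / (rep1@tp + rep1@fp + rep1@tn + rep1@fn))

  # perfect predictor
  rep2 <- classificationReport(c(10, 20, 90, 99), c(TRUE, TRUE, FALSE, FALSE),
                               cutoff = 50)
  expect_equal(rep2@accuracy, 1)
  expect_equal(rep2@ppv, 1)
  expect_equal(rep2@npv, 1)

  # cutoff below all scores: everything predicted acceptable
  expect_warning(
    rep3 <- classificationReport(c(10, 20, 30), c(TRUE, FALSE, TRUE),
                                 cutoff = 5),
    "PPV")
  expect_equal(rep3@sensitivity, 0)
  expect_true(is.nan(rep3@ppv))
})

test_that("reports serialize to JSON with all metrics present", {
  rep1 <- classificationReport(c(10, 80, 90, 20), c(TRUE, FALSE, FALSE, TRUE),
                               cutoff = 50)
  path <- withr::local_tempfile(fileext = ".json")
  writeReport(rep1, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$accuracy, 1)
  expect_named(back, c("cutoff", "tp", "fp", "tn", "fn", "accuracy",
                       "sensitivity", "specificity", "ppv", "npv"))
})

test_that("Kruskal-Wallis matches the tie-corrected formula oracle", {
  sep <- list(c(1, 1), c(2, 2), c(3, 3))
  got <- kruskalWallis(sep)
  expect_equal(got$H, oracleKruskalH(sep), tolerance = 1e-12)
  expect_equal(got$df, 2)

  # identical composition in both groups: H near 0
  same <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_lt(kruskalWallis(same)$H, 1e-10)

  withr::with_seed(95, {
    for (i in 1:10) {
      k <- sample(2:4, 1)
      groups <- lapply(seq_len(k), function(g)
        sample(1:6, sample(3:10, 1), replace = TRUE))  # heavy ties
      if (var(unlist(groups)) == 0) next
      got <- kruskalWallis(groups)
      expect_equal(got$H, oracleKruskalH(groups), tolerance = 1e-10)
      expect_equal(got$p_value, pchisq(got$H, k - 1, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  })

  expect_error(kruskalWallis(list(1:3)), "at least 2")
  expect_error(kruskalWallis(list(1:3, numeric())), "non-empty")
})
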