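test_that("split_cohort reproduces the 266/133 protocol and is seeded", {
  cohort <- tibble::tibble(id = 1:399, pt_group = rep(1:2, c(179, 220)))
  parts <- split_cohort(cohort, train_fraction = 2 / 3, seed = 5)
  expect_equal(nrow(parts$train), 266)
  expect_equal(nrow(parts$validation), 133)
  parts2 <- split_cohort(cohort, train_fraction = 2 / 3, seed = 5)
  expect_identical(parts, parts2)
  expect_error(split_cohort(cohort, train_fraction = 1.0))
  strat <- split_cohort(cohort, seed = 5, stratified = TRUE)
  tr_ratio <- mean(strat$train$pt_group == 2)
  expect_equal(tr_ratio, 220 / 399, tolerance = 0.01)
})

test_that("confusion counts follow the ED-positive convention", {
  cc <- confusion_counts(c("ED", "ED", "OCD", "OCD"), c("ED", "OCD", "OCD", "ED"))
  expect_identical(c(cc$tp, cc$fn, cc$tn, cc$fp), rep(1L, 4))
  perfect <- confusion_counts(c(2, 1, 2), c(2, 1, 2))
  expect_identical(perfect$fp + perfect$fn, 0L)
  expect_error(confusion_counts(character(0), character(0)))
  expect_error(confusion_counts("ED", c("ED", "OCD")))
})

test_that("sensitivity and specificity are the published ratios", {
  cc <- list(tp = 3, fn = 1, tn = 1, fp = 3, p = 4, n = 4)
  class(cc) <- "confusion_counts"
  expect_equal(sensitivity(cc), 0.75)
  expect_equal(specificity(cc), 0.25)
  none <- confusion_counts(c("OCD", "OCD"), c("OCD", "ED"))
  expect_error(sensitivity(none), class = "fuzzystage_undefined_value")
  all_pos <- confusion_counts(c("ED", "ED"), c("OCD", "ED"))
  expect_error(specificity(all_pos), class = "fuzzystage_undefined_value")
})

test_that("roc_curve matches closed-form cases", {
  perfect <- roc_curve(c(0.9, 0.8, 0.1, 0.2), c("ED", "ED", "OCD", "OCD"))
  expect_equal(perfect$auc, 1.0)
  expect_equal(perfect$optimal$fpr, 0)
  expect_equal(perfect$optimal$tpr, 1)
  flat <- roc_curve(rep(0.5, 6), rep(c("ED", "OCD"), 3))
  expect_equal(flat$auc, 0.5)
  expect_equal(nrow(flat$points), 2)
  # positives {0.9, 0.8, 0.4}, negatives {0.7, 0.3, 0.2} -> AUC 8/9
  scores <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  truth <- c("ED", "ED", "ED", "OCD", "OCD", "OCD")
  roc <- roc_curve(scores, truth)
  expect_equal(roc$auc, 8 / 9)
  # optimal point by the smaller-FPR tie-break
  expect_equal(roc$optimal$fpr, 0)
  expect_equal(roc$optimal$tpr, 2 / 3)
  # uninformative scores sit at (0, 0) after the tie-break
  expect_equal(flat$optimal$fpr, 0)
  expect_equal(flat$optimal$tpr, 0)
  expect_error(roc_curve(c(1, 2), c("ED", "ED")))
})

test_that("trapezoid AUC equals the Mann-Whitney pair statistic on random instances", {
  withr::with_seed(77, {
    for (rep in 1:25) {
      n <- sample(4:12, 1)
      truth <- c("ED", "OCD", sample(c("ED", "OCD"), n - 2, replace = TRUE))
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
      roc <- roc_curve(scores, truth)
      expect_equal(roc$auc, oracle_auc(scores, truth == "ED"), tolerance = 1e-12)
    }
  })
})

test_that("AUC is invariant under monotone transforms and flips on relabeling", {
  withr::with_seed(31, {
    scores <- runif(40)
    truth <- sample(c("ED", "OCD"), 40, replace = TRUE, prob = c(0.55, 0.45))
  })
  auc <- roc_curve(scores, truth)$auc
  expect_equal(roc_curve(exp(3 * scores), truth)$auc, auc, tolerance = 1e-12)
  expect_equal(roc_curve(pmin(pmax(scores - 1, -1), 1), truth)$auc, auc,
               tolerance = 1e-12)
  flipped <- ifelse(truth == "ED", "OCD", "ED")
  expect_equal(roc_curve(scores, flipped)$auc, 1 - auc, tolerance = 1e-12)
})

test_that("ROC endpoints behave at extreme thresholds", {
  withr::with_seed(9, {
    scores <- rnorm(30)
    truth <- sample(c("ED", "OCD"), 30, replace = TRUE)
  })
  roc <- roc_curve(scores, truth)
  expect_equal(unlist(roc$points[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc$points[nrow(roc$points), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
})

test_that("McNemar test matches the chi-square and exact oracles", {
  truth <- rep(c("ED", "OCD"), c(4, 4))
  expect_equal(mcnemar_test(truth, truth)$p_value, 1.0)
  # b = c > 0: statistic 0, p = 1
  pred <- c("OCD", "ED", "ED", "ED", "ED", "OCD", "OCD", "OCD")
  mc <- mcnemar_test(truth, pred)
  expect_equal(mc$b, 1)
  expect_equal(mc$c, 1)
  expect_equal(mc$statistic, 0)
  expect_equal(mc$p_value, 1.0)
  # b = 10, c = 2
  truth2 <- rep(c("ED", "OCD"), c(20, 20))
  pred2 <- c(rep("OCD", 10), rep("ED", 10), rep("ED", 2), rep("OCD", 18))
  mc2 <- mcnemar_test(truth2, pred2)
  expect_equal(mc2$statistic, 64 / 12)
  expect_equal(mc2$p_value, stats::pchisq(64 / 12, 1, lower.tail = FALSE))
  expect_equal(mc2$p_value, 0.0209, tolerance = 2e-3)
  exact <- mcnemar_test(truth2, pred2, method = "exact")
  expect_equal(exact$p_value, stats::binom.test(10, 12, 0.5)$p.value)
})

test_that("evaluate_model bundles self-consistent report fields", {
  withr::with_seed(15, {
    truth <- sample(c("ED", "OCD"), 60, replace = TRUE)
    scores <- runif(60) + 0.5 * (truth == "ED")
  })
  ev <- evaluate_model(scores, truth)
  expect_equal(ev$roc$optimal$tpr, ev$sensitivity)
  expect_equal(ev$roc$optimal$fpr, 1 - ev$specificity)
  row <- tidy(ev)
  expect_named(row, c("auc", "optimal_fpr", "optimal_tpr", "optimal_threshold",
                      "sensitivity", "specificity", "mcnemar_p"))
  perfect <- evaluate_model(c(1, 1, 0, 0), c("ED", "ED", "OCD", "OCD"))
  expect_equal(perfect$roc$auc, 1)
  expect_equal(perfect$mcnemar$p_value, 1)
})

test_that("bootstrap AUC interval is seeded and brackets the point estimate", {
  withr::with_seed(3, {
    truth <- sample(c("ED", "OCD"), 80, replace = TRUE)
    scores <- runif(80) + 0.6 * (truth == "ED")
  })
  ci <- auc_ci(scores, truth, resamples = 200, seed = 4)
  expect_lte(ci$lower, ci$auc)
  expect_gte(ci$upper, ci$auc)
  expect_identical(ci, auc_ci(scores, truth, resamples = 200, seed = 4))
})
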