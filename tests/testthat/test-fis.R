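test_that("Gaussian membership evaluation matches its closed form", {
  expect_equal(mf_eval(2, center = 2, width = 0.5), 1.0)
  expect_equal(mf_eval(2.5, center = 2, width = 0.5), exp(-0.5))
  expect_equal(mf_eval(3.5, center = 2, width = 0.5), exp(-4.5))
  expect_error(mf_eval(1, center = 0, width = 0))
})

test_that("rule firing is the product t-norm of the membership degrees", {
  rule <- list(center = c(1, 2), width = c(1, 1), coef = 0)
  expect_equal(rule_firing(rule, c(1, 2)), 1.0)
  # two inputs each at degree 0.5
  x_half <- c(1 + sqrt(2 * log(2)) * 1, 2 + sqrt(2 * log(2)) * 1)
  expect_equal(rule_firing(rule, x_half), 0.25)
  expect_equal(rule_firing(rule, c(1, 2e4)), 0)
  expect_error(rule_firing(rule, c(1, 2, 3)))
})

test_that("inference is the normalized weighted average of rule consequents", {
  # single rule with constant consequent returns the constant
  single <- sugeno_fis(list(list(center = 1, width = 1, coef = 5, class_tag = "OCD")),
                       "x", rbind(0, 2))
  expect_equal(fis_infer(single, 0.3)$y_hat, 5)
  # equal firing of consequents 1 and 2 -> 1.5
  fis <- toy_two_rule_fis(c1 = 2, c2 = 6, w1 = 1, w2 = 1)
  expect_equal(fis_infer(fis, 4)$y_hat, 1.5)
  # w = (0.8, 0.2), f = (1, 2) -> 1.2, checked through the detail output
  det <- fis_infer(fis, 4, detail = TRUE)
  expect_equal(sum(det$detail$normalized), 1)
  manual_x <- 2 + sqrt(-2 * log(0.8))  # firing 0.8 for rule 1
  det2 <- fis_infer(fis, manual_x, detail = TRUE)
  w <- det2$detail$firing
  expect_equal(det2$y_hat, sum(w / sum(w) * c(1, 2)))
  # hand-built weighted average oracle
  expect_equal(sum(c(0.8, 0.2) / 1 * c(1, 2)), 1.2)
})

test_that("inference output is a convex combination of the consequents", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      fis <- sugeno_fis(list(
        list(center = runif(3, 0, 5), width = runif(3, 0.3, 2),
             coef = rnorm(4), class_tag = "OCD"),
        list(center = runif(3, 0, 5), width = runif(3, 0.3, 2),
             coef = rnorm(4), class_tag = "ED")
      ), paste0("x", 1:3), rbind(rep(0, 3), rep(5, 3)))
      x <- runif(3, 0, 5)
      det <- fis_infer(fis, x, detail = TRUE)
      expect_gte(det$y_hat, min(det$detail$consequent) - 1e-12)
      expect_lte(det$y_hat, max(det$detail$consequent) + 1e-12)
      expect_equal(sum(det$detail$normalized), 1, tolerance = 1e-12)
    }
  })
})

test_that("inference is continuous in the input (finite-difference smoke test)", {
  fis <- toy_two_rule_fis()
  xs <- seq(0, 8, by = 0.01)
  ys <- fis_infer(fis, matrix(xs, ncol = 1))$y_hat
  expect_lt(max(abs(diff(ys))), 0.02)
})

test_that("underflow of all firing strengths falls back to the nearest rule", {
  fis <- toy_two_rule_fis(w1 = 0.01, w2 = 0.01)
  expect_warning(out <- fis_infer(fis, 400), "underflow")
  expect_equal(out$y_hat, 2)  # rule 2 (center 6) is nearest to x = 400
})

test_that("fis_from_fcm builds one rule per cluster with positive widths", {
  cohort <- generate_cohort(cohort_spec(n = 200, seed = 6))
  grouped <- normalize_cohort(cohort)
  x <- as.matrix(grouped[INPUT_COLS])
  fit <- fcm_fit(x, c = 2, seed = 6)
  fis <- fis_from_fcm(fit, grouped$pt_group)
  expect_length(fis$rules, 2)
  for (r in fis$rules) {
    expect_true(all(r$width > 0))
    expect_length(r$coef, 6)
  }
  expect_true(all(purrr::map_chr(fis$rules, "class_tag") %in% c("OCD", "ED")))
})

test_that("the initial FIS classifies cluster-core points of a separable cohort", {
  # two crisply separated groups in the grouped-input space
  withr::with_seed(14, {
    ocd <- cbind(3, 3, rnorm(40, 2, 0.3), rnorm(40, 7, 0.3), 1)
    ed <- cbind(5, 5, rnorm(40, 5, 0.3), rnorm(40, 10, 0.3), 5)
  })
  x <- rbind(ocd, ed)
  colnames(x) <- INPUT_COLS
  y <- rep(c(1, 2), each = 40)
  fit <- fcm_fit(x, c = 2, seed = 14)
  # constant Gleason columns make the consequent system singular: the
  # documented ridge fallback engages
  expect_warning(fis <- fis_from_fcm(fit, y), "ridge")
  core <- rbind(colMeans(ocd), colMeans(ed))
  colnames(core) <- INPUT_COLS
  scores <- fis_infer(fis, core)$y_hat
  expect_lt(scores[1], 1.5)
  expect_gt(scores[2], 1.5)
})

test_that("FIS JSON serialization round-trips bit-exactly", {
  cohort <- generate_cohort(cohort_spec(n = 120, seed = 5))
  grouped <- normalize_cohort(cohort)
  x <- as.matrix(grouped[INPUT_COLS])
  fis <- fis_from_fcm(fcm_fit(x, seed = 5), grouped$pt_group)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_fis(fis, p1)
  back <- read_fis(p1)
  expect_equal(back$rules, fis$rules, tolerance = 0)
  expect_identical(back$input_names, fis$input_names)
  write_fis(back, p2)
  expect_identical(readr::read_file(p1), readr::read_file(p2))
})
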