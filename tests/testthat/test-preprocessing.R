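test_that("PSA grouping follows the published bins with half-open boundaries", {
  expect_identical(group_psa(c(1.00, 9.84, 20.0, 107.00)), c(1L, 4L, 6L, 6L))
  # boundaries: lower bound of each bin belongs to that bin
  expect_identical(group_psa(c(2.6, 4.1, 6.1, 10, 19.999, 2.5999)),
                   c(2L, 3L, 4L, 5L, 5L, 1L))
  expect_error(group_psa(-1), class = "fuzzystage_invalid_value")
  expect_error(group_psa("high"), class = "fuzzystage_invalid_value")
})

test_that("age grouping uses five-year bins with 70+ in the top group", {
  expect_identical(group_age(c(51.6, 77.0, 24.9, 70, 69.99)),
                   c(7L, 11L, 1L, 11L, 10L))
  expect_error(group_age(0), class = "fuzzystage_invalid_value")
})

test_that("clinical T grouping matches the published table", {
  expect_identical(group_clinical_t(c("T2b", "T1c", "T4", "T1a", "T1b",
                                      "T2a", "T2c", "T3a", "T3b")),
                   c(3L, 1L, 5L, 1L, 1L, 2L, 4L, 5L, 5L))
  expect_error(group_clinical_t("T9"), class = "fuzzystage_vocabulary_error")
  expect_warning(res <- group_clinical_t("T2"), "laterality")
  expect_identical(res, 2L)
})

test_that("pathological T grouping yields the binary OCD/ED outcome", {
  expect_identical(group_pathological_t(c("T2a", "T3a", "T2", "pT2b", "pT4")),
                   c(1L, 2L, 1L, 1L, 2L))
  expect_error(group_pathological_t("T1c"), class = "fuzzystage_vocabulary_error")
  expect_error(group_pathological_t("T5"), class = "fuzzystage_vocabulary_error")
})

test_that("the five published worked normalization rows reproduce exactly", {
  raw <- tibble::tibble(
    primary_gleason = rep(3L, 5), secondary_gleason = rep(3L, 5),
    psa = c(1.00, 1.70, 2.05, 2.09, 2.20),
    age = c(51.6, 77.0, 55.2, 61.1, 57.0),
    clinical_t = c("T2b", "T2b", "T2a", "T1c", "T1c"),
    pathological_t = c("T2a", "T2c", "pT2b", "pT2b", "T3a")
  )
  grouped <- normalize_cohort(raw)
  expect_identical(grouped$primary_gleason, rep(3L, 5))
  expect_identical(grouped$secondary_gleason, rep(3L, 5))
  expect_identical(grouped$psa_group, rep(1L, 5))
  expect_identical(grouped$age_group, c(7L, 11L, 8L, 9L, 8L))
  expect_identical(grouped$clinical_t_group, c(3L, 3L, 2L, 1L, 1L))
  expect_identical(grouped$pt_group, c(1L, 1L, 1L, 1L, 2L))
})

test_that("grouping functions are monotone and stay in their ordinal ranges", {
  withr::with_seed(101, {
    psa <- sort(runif(200, 0.1, 120))
    age <- sort(runif(200, 20, 90))
  })
  expect_true(all(diff(group_psa(psa)) >= 0))
  expect_true(all(diff(group_age(age)) >= 0))
  expect_true(all(group_psa(psa) %in% 1:6))
  expect_true(all(group_age(age) %in% 1:11))
  t_ladder <- c("T1a", "T1b", "T1c", "T2a", "T2b", "T2c", "T3a", "T3b", "T4")
  expect_true(all(diff(group_clinical_t(t_ladder)) >= 0))
})

test_that("normalization is missing-intolerant but pathological_t is optional", {
  raw <- tibble::tibble(primary_gleason = 3, secondary_gleason = 4,
                        psa = 5, age = 60, clinical_t = "T1c")
  grouped <- normalize_cohort(raw)
  expect_false("pt_group" %in% names(grouped))
  expect_error(normalize_cohort(raw[-2]), class = "fuzzystage_schema_error")
})

test_that("read_cohort parses CSV fixtures and reports schema problems", {
  path <- withr::local_tempfile(fileext = ".csv")
  cohort <- generate_cohort(cohort_spec(n = 5, seed = 2))
  readr::write_csv(cohort, path)
  records <- read_cohort(path)
  expect_equal(nrow(records), 5)
  expect_equal(records$clinical_t, cohort$clinical_t)

  # missing PSA column
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(cohort[setdiff(names(cohort), "psa")], path2)
  expect_error(read_cohort(path2), class = "fuzzystage_schema_error")

  # empty file (header only)
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(cohort[0, ], path3)
  expect_equal(nrow(read_cohort(path3)), 0)

  # column remapping
  path4 <- withr::local_tempfile(fileext = ".csv")
  renamed <- dplyr::rename(cohort, psa_ng_ml = psa)
  readr::write_csv(renamed, path4)
  expect_equal(nrow(read_cohort(path4, col_map = c(psa = "psa_ng_ml"))), 5)

  # unparsable cell reported with its line number
  path5 <- withr::local_tempfile(fileext = ".csv")
  broken <- cohort
  broken$psa <- as.character(broken$psa)
  broken$psa[3] <- "n/a"
  readr::write_csv(broken, path5)
  expect_error(read_cohort(path5), "line", class = "fuzzystage_parse_error")
})

test_that("cohort_summary reproduces the published discordance arithmetic", {
  # reconstruct a grouped cohort with exactly the published marginal counts
  grouped <- tibble::tibble(
    primary_gleason = rep(3:5, c(205, 173, 21)),
    secondary_gleason = rep(3:5, c(159, 185, 55)),
    psa_group = rep(1:6, c(16, 33, 124, 124, 67, 35)),
    age_group = rep(1:11, c(0, 0, 0, 0, 5, 22, 68, 97, 100, 76, 31)),
    clinical_t_group = rep(1:5, c(204, 53, 53, 42, 47)),
    pt_group = rep(1:2, c(179, 220))
  )
  s <- cohort_summary(grouped)
  expect_identical(s$discordant_n, 173L)
  expect_equal(s$discordant_pct, 43.36, tolerance = 0.01)
  # grouped-PSA mean matches the published total row
  psa_mean <- s$stats$mean[s$stats$variable == "psa_group"]
  expect_equal(psa_mean, 3.75, tolerance = 0.005)
  # a cohort where clinical group 5 coincides with ED has no discordance
  aligned <- grouped
  aligned$clinical_t_group <- ifelse(aligned$pt_group == 2, 5L, 1L)
  expect_identical(cohort_summary(aligned)$discordant_n, 0L)
  expect_error(cohort_summary(grouped[0, ]))
})
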