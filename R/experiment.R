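# End-to-end experiment mirroring the study protocol: normalize, split
# once, seed a two-rule TSK system from fuzzy c-means, tune it by ANFIS,
# and evaluate the neuro-fuzzy model, the FCM-only classifier and the AJCC
# nomogram baseline on the same validation subset.

#' Simulate a cohort and optionally write it to disk
#'
#' @param spec A [cohort_spec()].
#' @param path Optional CSV output path; a provenance JSON (spec, seed,
#'   package version) is written next to it.
#' @return The raw cohort tibble, invisibly when written.
#' @export
simulate_cohort <- function(spec = cohort_spec(), path = NULL) {
  cohort <- generate_cohort(spec)
  if (!is.null(path)) {
    readr::write_csv(cohort, path)
    prov <- list(
      spec = list(n = spec$n, ed_prevalence = spec$ed_prevalence,
                  marginals = spec$marginals,
                  class_shift = as.list(spec$class_shift), seed = spec$seed),
      package = "fuzzystage",
      version = as.character(utils::packageVersion("fuzzystage"))
    )
    jsonlite::write_json(prov, paste0(sub("\\.csv$", "", path), "_provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(cohort))
  }
  cohort
}

#' Run the full staging-prediction experiment
#'
#' Normalizes the raw cohort, performs one seeded train/validation split
#' (shared by all models), fits fuzzy c-means on the grouped training
#' inputs, seeds and ANFIS-trains the Sugeno system, then evaluates three
#' classifiers on the same validation subset: the trained neuro-fuzzy model
#' (score = extra-prostatic likelihood), the FCM-only classifier (score =
#' membership in the extra-prostatic cluster) and the AJCC nomogram
#' (ordinal stage-group score from the raw variables, defaulting N0/M0).
#'
#' @param cohort Raw cohort data frame (see [read_cohort()]) carrying
#'   `pathological_t`.
#' @param seed Integer seed for the split, clustering and training.
#' @param train_fraction Training fraction (default 2/3).
#' @param stratified Stratify the split by outcome?
#' @param epochs ANFIS epoch cap.
#' @param fcm_m Fuzzifier for the clustering step.
#' @param mcnemar_method Passed to [mcnemar_test()].
#' @return An `experiment_report`: `comparison` (one tidy row per model),
#'   `evaluations` (named list of [evaluate_model()] objects), the trained
#'   `model`, the `split` sizes and the `cutoff` used.
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_spec(n = 150, seed = 3))
#' report <- run_experiment(cohort, seed = 3, epochs = 15)
#' report$comparison
#' }
run_experiment <- function(cohort, seed = 1L, train_fraction = 2 / 3,
                           stratified = FALSE, epochs = 100, fcm_m = 2,
                           mcnemar_method = "chi2") {
  grouped <- normalize_cohort(cohort)
  if (!"pt_group" %in% names(grouped)) {
    abort("run_experiment requires outcomes (`pathological_t`).")
  }
  cohort <- as_tibble(cohort)
  cohort$.row <- seq_len(nrow(cohort))
  grouped$.row <- cohort$.row

  parts <- split_cohort(grouped, train_fraction = train_fraction, seed = seed,
                        stratified = stratified)
  input_cols <- c("primary_gleason", "secondary_gleason", "psa_group",
                  "age_group", "clinical_t_group")
  x_train <- as.matrix(parts$train[input_cols])
  x_valid <- as.matrix(parts$validation[input_cols])
  y_train <- parts$train$pt_group
  y_valid <- parts$validation$pt_group
  truth <- ifelse(y_valid == 2, "ED", "OCD")

  # neuro-fuzzy pipeline
  fit <- fcm_fit(x_train, c = 2, m = fcm_m, seed = seed)
  fis0 <- fis_from_fcm(fit, y_train)
  trained <- anfis_train(fis0, x_train, y_train, epochs = epochs)
  train_scores <- predict_score(trained, x_train)$score
  cutoff <- roc_curve(train_scores, y_train)$optimal$threshold
  nf_scores <- predict_score(trained, x_valid)$score

  # FCM-only classifier: validation membership in the ED-assigned cluster
  cls <- fcm_classify(fit, y_train)
  u_valid <- fcm_membership(x_valid, fit$centers, m = fcm_m)
  ed_cols <- which(cls$cluster_class == "ED")
  fcm_scores <- if (length(ed_cols) == 0) rep(0, nrow(u_valid)) else
    rowSums(u_valid[, ed_cols, drop = FALSE])

  # nomogram baseline on the raw validation records (N0/M0 defaults)
  raw_valid <- cohort[match(parts$validation$.row, cohort$.row), ]
  nomo_scores <- nomogram_score(
    t_code = raw_valid$clinical_t,
    psa = raw_valid$psa,
    gleason_sum = raw_valid$primary_gleason + raw_valid$secondary_gleason
  )

  evaluations <- list(
    neuro_fuzzy = evaluate_model(nf_scores, truth, mcnemar_method),
    fcm = evaluate_model(fcm_scores, truth, mcnemar_method),
    nomogram = evaluate_model(nomo_scores, truth, mcnemar_method)
  )
  comparison <- purrr::imap_dfr(evaluations, function(ev, nm) {
    dplyr::bind_cols(tibble(model = nm), tidy(ev))
  })
  structure(
    list(comparison = comparison, evaluations = evaluations,
         model = trained, initial_fis = fis0, fcm = fit, cutoff = cutoff,
         split = c(train = nrow(parts$train), validation = nrow(parts$validation)),
         seed = seed),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Staging experiment (seed %s): %d training / %d validation records\n",
              format(x$seed), x$split["train"], x$split["validation"]))
  print(as.data.frame(x$comparison), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
tidy.experiment_report <- function(x, ...) x$comparison

#' Write an experiment report to JSON
#'
#' @param report An [run_experiment()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  doc <- list(
    seed = report$seed,
    split = as.list(report$split),
    cutoff = report$cutoff,
    comparison = report$comparison
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
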