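# Binary-classifier evaluation: confusion counts with extra-prostatic
# disease as the positive class, sensitivity/specificity, the ROC curve
# with trapezoidal AUC and the Youden-optimal operating point, the McNemar
# paired test, and the train/validation split protocol.

#' Split a cohort into training and validation subsets
#'
#' Seeded random partition with `round(n * train_fraction)` training
#' records; the stratified option preserves the class ratio within each
#' subset.
#'
#' @param data Data frame of records.
#' @param train_fraction Fraction assigned to training (default 2/3).
#' @param seed Integer seed.
#' @param stratified Preserve the class ratio per subset?
#' @param class_col Column holding the outcome (used when `stratified`).
#' @return A list with tibbles `train` and `validation`.
#' @export
split_cohort <- function(data, train_fraction = 2 / 3, seed = 1L,
                         stratified = FALSE, class_col = "pt_group") {
  n <- nrow(data)
  if (n < 2) abort("Need at least 2 records to split.")
  n_train <- round(n * train_fraction)
  if (n_train < 1 || n_train >= n) {
    abort("`train_fraction` leaves an empty training or validation subset.")
  }
  idx <- withr::with_seed(seed, {
    if (stratified) {
      if (!class_col %in% names(data)) {
        abort(paste0("Stratification column `", class_col, "` not found."))
      }
      cls <- data[[class_col]]
      if (any(table(cls) < 1)) abort("Empty class under stratification.")
      unlist(lapply(split(seq_len(n), cls), function(ii) {
        k <- round(length(ii) * train_fraction)
        if (k < 1 || k >= length(ii)) abort("Empty class subset under stratification.")
        sample(ii, k)
      }), use.names = FALSE)
    } else {
      sample(n, n_train)
    }
  })
  list(train = as_tibble(data[sort(idx), , drop = FALSE]),
       validation = as_tibble(data[setdiff(seq_len(n), sort(idx)), , drop = FALSE]))
}

#' Confusion counts with extra-prostatic disease as the positive class
#'
#' @param truth,predicted Equal-length label vectors ("OCD"/"ED", factors,
#'   or 1/2 coding).
#' @return A `confusion_counts` list with `tp`, `fp`, `tn`, `fn`, `p`, `n`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) == 0) abort("Empty input.")
  if (length(truth) != length(predicted)) abort("Length mismatch.")
  truth <- as_class_label(truth)
  predicted <- as_class_label(predicted)
  out <- list(
    tp = sum(truth == "ED" & predicted == "ED"),
    fp = sum(truth == "OCD" & predicted == "ED"),
    tn = sum(truth == "OCD" & predicted == "OCD"),
    fn = sum(truth == "ED" & predicted == "OCD")
  )
  out$p <- out$tp + out$fn
  out$n <- out$fp + out$tn
  structure(out, class = "confusion_counts")
}

#' Sensitivity (true positive rate)
#'
#' @param counts A [confusion_counts()] object.
#' @return `tp / (tp + fn)`.
#' @export
sensitivity <- function(counts) {
  if (counts$p == 0) abort("Sensitivity undefined: no positive records.",
                           class = "fuzzystage_undefined_value")
  counts$tp / counts$p
}

#' Specificity (true negative rate)
#'
#' @param counts A [confusion_counts()] object.
#' @return `tn / (tn + fp)`.
#' @export
specificity <- function(counts) {
  if (counts$n == 0) abort("Specificity undefined: no negative records.",
                           class = "fuzzystage_undefined_value")
  counts$tn / counts$n
}

#' ROC curve, AUC and optimal operating point
#'
#' Sweeps a decision threshold over every distinct score (ties grouped,
#' boundary scores classify positive), accumulating (FPR, TPR) from (0, 0)
#' to (1, 1). AUC is the trapezoidal integral; the optimal point maximizes
#' Youden's J = TPR - FPR, ties broken toward the smaller FPR.
#'
#' @param scores Numeric classifier scores (larger = more extra-prostatic).
#' @param truth True labels ("OCD"/"ED" or 1/2); ED is positive.
#' @return A `roc_analysis` object with `points` (tibble of threshold, fpr,
#'   tpr), `auc` and `optimal`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as_class_label(truth)
  if (length(scores) != length(truth)) abort("Length mismatch.")
  if (any(!is.finite(scores))) abort("Scores must be finite.")
  pos <- truth == "ED"
  if (!any(pos) || all(pos)) abort("Both classes must be present.")
  thresholds <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(scores[!pos] >= t), numeric(1))
  points <- tibble(threshold = c(Inf, thresholds), fpr = c(0, fpr), tpr = c(0, tpr))
  if (points$fpr[nrow(points)] != 1 || points$tpr[nrow(points)] != 1) {
    points <- dplyr::bind_rows(points, tibble(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + tail(points$tpr, -1)) / 2)
  roc <- structure(list(points = points, auc = auc), class = "roc_analysis")
  roc$optimal <- optimal_point(roc)
  roc
}

#' Optimal ROC operating point (Youden's J)
#'
#' @param roc A [roc_curve()] result.
#' @return A list with `fpr`, `tpr` and `threshold`.
#' @export
optimal_point <- function(roc) {
  pts <- roc$points
  j <- pts$tpr - pts$fpr
  # numeric ties in J (e.g. 2/3 computed two ways) count as exact ties
  best <- which(j >= max(j) - 1e-9)
  best <- best[which.min(pts$fpr[best])]
  list(fpr = pts$fpr[best], tpr = pts$tpr[best], threshold = pts$threshold[best])
}

#' @export
print.roc_analysis <- function(x, ...) {
  cat(sprintf("ROC analysis: AUC %.3f; optimal point FPR %.3f, TPR %.3f (threshold %.4g)\n",
              x$auc, x$optimal$fpr, x$optimal$tpr, x$optimal$threshold))
  invisible(x)
}

#' @export
tidy.roc_analysis <- function(x, ...) x$points

#' @export
glance.roc_analysis <- function(x, ...) {
  tibble(auc = x$auc, optimal_fpr = x$optimal$fpr, optimal_tpr = x$optimal$tpr,
         optimal_threshold = x$optimal$threshold)
}

#' Plot a ROC curve
#'
#' @param object A [roc_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_analysis <- function(object, ...) {
  ggplot(object$points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_point(data = tibble(fpr = object$optimal$fpr, tpr = object$optimal$tpr),
               colour = "red", size = 2) +
    labs(x = "false positive rate (1 - specificity)",
         y = "true positive rate (sensitivity)",
         title = sprintf("AUC = %.3f", object$auc)) +
    theme_minimal()
}

#' Bootstrap confidence interval for the AUC
#'
#' Seeded nonparametric bootstrap over records; percentile interval.
#'
#' @param scores,truth As in [roc_curve()].
#' @param conf Confidence level.
#' @param resamples Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return A tibble with `auc`, `lower`, `upper`, `conf`, `resamples`.
#' @export
auc_ci <- function(scores, truth, conf = 0.95, resamples = 2000, seed = 1L) {
  truth <- as_class_label(truth)
  base_auc <- roc_curve(scores, truth)$auc
  boots <- withr::with_seed(seed, {
    vapply(seq_len(resamples), function(i) {
      idx <- sample(length(scores), replace = TRUE)
      if (length(unique(truth[idx])) < 2) return(NA_real_)
      roc_curve(scores[idx], truth[idx])$auc
    }, numeric(1))
  })
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  tibble(auc = base_auc, lower = unname(qs[1]), upper = unname(qs[2]),
         conf = conf, resamples = resamples)
}

#' McNemar paired test of predictions against truth
#'
#' Discordant counts are `b` (positives missed, i.e. FN) and `c` (negatives
#' called positive, i.e. FP). The default approximate chi-square statistic
#' is `(b - c)^2 / (b + c)` without continuity correction, with a p-value
#' from the chi-square distribution on 1 df; `b + c = 0` gives statistic 0
#' and p = 1. The exact method uses a two-sided binomial test of `b`
#' successes in `b + c` trials at probability 1/2.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param method `"chi2"` (default) or `"exact"`.
#' @return A list with `statistic`, `p_value`, `b`, `c` and `method`.
#' @export
mcnemar_test <- function(truth, predicted, method = c("chi2", "exact")) {
  method <- match.arg(method)
  cc <- confusion_counts(truth, predicted)
  b <- cc$fn
  c_ <- cc$fp
  if (b + c_ == 0) {
    return(list(statistic = 0, p_value = 1, b = b, c = c_, method = method))
  }
  if (method == "chi2") {
    stat <- (b - c_)^2 / (b + c_)
    list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         b = b, c = c_, method = method)
  } else {
    bt <- stats::binom.test(b, b + c_, p = 0.5)
    list(statistic = NA_real_, p_value = bt$p.value, b = b, c = c_, method = method)
  }
}

#' Evaluate a scored classifier
#'
#' Bundles the ROC analysis, sensitivity and specificity at the
#' Youden-optimal threshold, and the McNemar test of the thresholded labels
#' against the truth.
#'
#' @param scores,truth As in [roc_curve()].
#' @param mcnemar_method Passed to [mcnemar_test()].
#' @return A `model_evaluation` object.
#' @export
evaluate_model <- function(scores, truth, mcnemar_method = "chi2") {
  truth <- as_class_label(truth)
  roc <- roc_curve(scores, truth)
  labels <- classify_stage(scores, roc$optimal$threshold)
  cc <- confusion_counts(truth, labels)
  mc <- mcnemar_test(truth, labels, method = mcnemar_method)
  structure(
    list(roc = roc, confusion = cc,
         sensitivity = sensitivity(cc), specificity = specificity(cc),
         mcnemar = mc),
    class = "model_evaluation"
  )
}

#' @export
print.model_evaluation <- function(x, ...) {
  print(x$roc)
  cat(sprintf("At optimal threshold: sensitivity %.3f, specificity %.3f; McNemar p = %.3f\n",
              x$sensitivity, x$specificity, x$mcnemar$p_value))
  invisible(x)
}

#' @export
tidy.model_evaluation <- function(x, ...) {
  tibble(auc = x$roc$auc,
         optimal_fpr = x$roc$optimal$fpr,
         optimal_tpr = x$roc$optimal$tpr,
         optimal_threshold = x$roc$optimal$threshold,
         sensitivity = x$sensitivity,
         specificity = x$specificity,
         mcnemar_p = x$mcnemar$p_value)
}

#' @export
glance.model_evaluation <- tidy.model_evaluation
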