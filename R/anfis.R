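# Hybrid ANFIS training of a Sugeno FIS: per epoch the consequent
# coefficients are solved globally by least squares given the current
# premises, then every membership-function center and width takes a
# gradient-descent step on the squared output error. A premise step that
# would increase the training RMSE is rolled back and the step size shrunk,
# so the recorded RMSE trace is non-increasing.

#' Root mean square error
#'
#' @param predictions,targets Equal-length numeric vectors.
#' @return `sqrt(mean((predictions - targets)^2))`.
#' @export
rmse <- function(predictions, targets) {
  if (length(predictions) == 0 || length(predictions) != length(targets)) {
    abort("`predictions` and `targets` must be non-empty and of equal length.")
  }
  sqrt(mean((predictions - targets)^2))
}

# Squared-error gradient of the TSK output with respect to every premise
# parameter. Returns list(center = k x p, width = k x p).
premise_gradient <- function(fis, x, y) {
  n <- nrow(x); k <- length(fis$rules); p <- ncol(x)
  w <- matrix(vapply(fis$rules, rule_firing, numeric(n), x = x), nrow = n)
  f <- matrix(vapply(fis$rules, rule_consequent, numeric(n), x = x), nrow = n)
  wsum <- rowSums(w)
  wsum[wsum <= 0] <- .Machine$double.xmin
  y_hat <- rowSums(w * f) / wsum
  resid <- y_hat - y                       # dE/dy_hat per record (x2 absorbed)
  dy_dw <- (f - y_hat) / wsum              # n x k
  g_center <- matrix(0, k, p)
  g_width <- matrix(0, k, p)
  for (i in seq_len(k)) {
    r <- fis$rules[[i]]
    common <- 2 * resid * dy_dw[, i] * w[, i]
    for (j in seq_len(p)) {
      diff <- x[, j] - r$center[j]
      g_center[i, j] <- sum(common * diff / r$width[j]^2)
      g_width[i, j] <- sum(common * diff^2 / r$width[j]^3)
    }
  }
  list(center = g_center, width = g_width)
}

apply_premise_step <- function(fis, grad, eta, width_floor = 0.01) {
  norm <- sqrt(sum(grad$center^2) + sum(grad$width^2))
  if (!is.finite(norm)) abort("Non-finite premise gradient; training aborted.")
  if (norm == 0) return(fis)
  for (i in seq_along(fis$rules)) {
    fis$rules[[i]]$center <- fis$rules[[i]]$center - eta * grad$center[i, ] / norm
    fis$rules[[i]]$width <- pmax(fis$rules[[i]]$width - eta * grad$width[i, ] / norm,
                                 width_floor)
  }
  fis
}

consequent_gradient_step <- function(fis, x, y, eta) {
  n <- nrow(x); k <- length(fis$rules)
  w <- matrix(vapply(fis$rules, rule_firing, numeric(n), x = x), nrow = n)
  f <- matrix(vapply(fis$rules, rule_consequent, numeric(n), x = x), nrow = n)
  wsum <- rowSums(w); wsum[wsum <= 0] <- .Machine$double.xmin
  wbar <- w / wsum
  resid <- rowSums(wbar * f) - y
  grads <- purrr::map(seq_len(k), function(i) {
    basis <- if (length(fis$rules[[i]]$coef) == 1L) matrix(1, n, 1) else cbind(1, x)
    drop(crossprod(basis, 2 * resid * wbar[, i]))
  })
  norm <- sqrt(sum(unlist(grads)^2))
  if (norm > 0 && is.finite(norm)) {
    for (i in seq_len(k)) {
      fis$rules[[i]]$coef <- fis$rules[[i]]$coef - eta * grads[[i]] / norm
    }
  }
  fis
}

train_rmse <- function(fis, x, y) rmse(fis_infer(fis, x)$y_hat, y)

#' Train a Sugeno FIS against known outcomes (ANFIS)
#'
#' Hybrid learning (default): per epoch, consequents are solved by global
#' least squares given the current premises, then all Gaussian centers and
#' widths take one gradient step of size `initial_step` along the
#' normalized gradient. The step grows by `step_increase` after four
#' consecutive error decreases and shrinks by `step_decrease` when a
#' proposed step would increase the error (the step is then rolled back, so
#' the recorded RMSE sequence is non-increasing). Training stops at the
#' epoch cap or once RMSE reaches `error_goal`.
#'
#' @param fis Initial [sugeno_fis()] (typically from [fis_from_fcm()]).
#' @param data Training inputs (`n x p` matrix or data frame of the grouped
#'   variables).
#' @param targets Numeric targets (1 = OCD, 2 = ED) or "OCD"/"ED" labels.
#' @param epochs Epoch cap.
#' @param error_goal RMSE stopping threshold.
#' @param method `"hybrid"` (least-squares consequents + gradient premises)
#'   or `"gradient"` (gradient descent on all parameters).
#' @param initial_step Initial premise step size.
#' @param step_increase,step_decrease Step adaptation factors.
#' @return An `anfis_fit` object: elements `fis` (trained), `initial_fis`,
#'   `rmse` (per-epoch trace), `stopped_reason` and `epochs_run`.
#' @export
anfis_train <- function(fis, data, targets, epochs = 100, error_goal = 0,
                        method = c("hybrid", "gradient"),
                        initial_step = 0.01, step_increase = 1.1,
                        step_decrease = 0.9) {
  stopifnot(inherits(fis, "sugeno_fis"), epochs >= 0, initial_step > 0)
  method <- match.arg(method)
  x <- as_input_matrix(fis, data)
  labels <- as_class_label_or_numeric(targets)
  y <- labels
  if (length(y) != nrow(x)) abort("`targets` must match the number of records.")
  initial_fis <- fis
  order <- if (length(fis$rules[[1]]$coef) == 1L) "constant" else "linear"
  q <- length(fis$rules[[1]]$coef) * length(fis$rules)
  if (method == "hybrid" && nrow(x) < q) {
    abort("Hybrid training needs at least as many records as consequent parameters.")
  }
  trace <- numeric(0)
  reason <- "epochs"
  step <- initial_step
  streak <- 0
  if (epochs > 0) {
    for (e in seq_len(epochs)) {
      if (method == "hybrid") fis <- solve_consequents(fis, x, y, order = order)
      current <- train_rmse(fis, x, y)
      grad <- premise_gradient(fis, x, y)
      candidate <- apply_premise_step(fis, grad, step)
      if (method == "gradient") {
        candidate <- consequent_gradient_step(candidate, x, y, step)
      } else {
        candidate <- solve_consequents(candidate, x, y, order = order)
      }
      proposed <- train_rmse(candidate, x, y)
      if (is.finite(proposed) && proposed <= current) {
        fis <- candidate
        current <- proposed
        streak <- streak + 1
        if (streak >= 4) { step <- step * step_increase; streak <- 0 }
      } else {
        step <- step * step_decrease
        streak <- 0
      }
      trace <- c(trace, current)
      if (current <= error_goal) { reason <- "error_goal"; break }
    }
  }
  structure(
    list(fis = fis, initial_fis = initial_fis, rmse = trace,
         stopped_reason = reason, epochs_run = length(trace),
         method = method, final_step = step),
    class = "anfis_fit"
  )
}

as_class_label_or_numeric <- function(targets) {
  if (is.numeric(targets)) return(as.numeric(targets))
  ifelse(as_class_label(targets) == "ED", 2, 1)
}

#' @export
print.anfis_fit <- function(x, ...) {
  cat("ANFIS fit (", x$method, "): ", x$epochs_run, " epochs, stopped on ",
      x$stopped_reason, "\n", sep = "")
  if (x$epochs_run > 0) {
    cat(sprintf("  training RMSE: %.6f -> %.6f\n", x$rmse[1], tail(x$rmse, 1)))
  }
  invisible(x)
}

#' @export
tidy.anfis_fit <- function(x, ...) {
  tibble(epoch = seq_along(x$rmse), rmse = x$rmse)
}

#' @export
glance.anfis_fit <- function(x, ...) {
  tibble(epochs_run = x$epochs_run,
         final_rmse = if (x$epochs_run > 0) tail(x$rmse, 1) else NA_real_,
         stopped_reason = x$stopped_reason, method = x$method)
}

#' Plot the per-epoch RMSE trace of an ANFIS fit
#'
#' @param object An [anfis_train()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.anfis_fit <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$epoch, y = .data$rmse)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "epoch", y = "training RMSE") +
    theme_minimal()
}

#' Score records with a (trained) FIS
#'
#' Returns the raw TSK output `y_hat` (targets coded 1 = organ-confined,
#' 2 = extra-prostatic) together with the normalized extra-prostatic
#' likelihood `score = clamp(y_hat - 1, 0, 1)`.
#'
#' @param fis A [sugeno_fis()] or [anfis_train()] result.
#' @param newdata Grouped records (matrix or data frame with the FIS input
#'   columns).
#' @return A tibble with columns `y_hat` and `score`.
#' @export
predict_score <- function(fis, newdata) {
  if (inherits(fis, "anfis_fit")) fis <- fis$fis
  out <- fis_infer(fis, newdata)
  out$score <- pmin(pmax(out$y_hat - 1, 0), 1)
  out
}

#' @export
predict.anfis_fit <- function(object, newdata, ...) {
  predict_score(object$fis, newdata)
}

#' Threshold a score into the binary stage label
#'
#' Extra-prostatic ("ED") iff `score >= cutoff` (boundary scores classify
#' as positive).
#'
#' @param score Numeric scores.
#' @param cutoff Decision threshold on the same scale as `score`.
#' @return Character vector of "OCD"/"ED".
#' @export
classify_stage <- function(score, cutoff) {
  stopifnot(!is.na(cutoff))  # +/-Inf allowed: degenerate all-one-class rules
  ifelse(score >= cutoff, "ED", "OCD")
}
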