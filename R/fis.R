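# Sugeno-type (Takagi-Sugeno-Kang) fuzzy inference system. Each rule has
# one Gaussian membership function per input and a first-order linear
# consequent f_i(x) = a_0 + sum_j a_j x_j. Inference is the standard
# five-layer forward pass: membership grades, product firing strengths,
# normalization, rule contributions, weighted-average output.

#' Evaluate a Gaussian membership function
#'
#' `exp(-(x - center)^2 / (2 width^2))`.
#'
#' @param x Numeric vector.
#' @param center Peak location.
#' @param width Standard-deviation-like width (> 0).
#' @return Membership degrees in `[0, 1]`.
#' @export
mf_eval <- function(x, center, width) {
  stopifnot(width > 0)
  exp(-(x - center)^2 / (2 * width^2))
}

#' Construct a Sugeno fuzzy inference system
#'
#' @param rules List of rules; each rule is a list with numeric vectors
#'   `center` and `width` (one Gaussian per input), numeric `coef`
#'   (`p + 1` linear consequent coefficients, intercept first; or a single
#'   constant for a zeroth-order system) and a `class_tag` ("OCD" or "ED").
#' @param input_names Character vector of input names.
#' @param ranges `2 x p` matrix of input lower/upper bounds.
#' @return A `sugeno_fis` object.
#' @export
sugeno_fis <- function(rules, input_names, ranges) {
  p <- length(input_names)
  stopifnot(length(rules) >= 1, ncol(ranges) == p)
  for (r in rules) {
    stopifnot(length(r$center) == p, length(r$width) == p,
              all(r$width > 0), all(is.finite(r$coef)),
              length(r$coef) %in% c(1L, p + 1L))
  }
  structure(list(rules = rules, input_names = input_names,
                 ranges = unname(as.matrix(ranges))),
            class = "sugeno_fis")
}

#' @export
print.sugeno_fis <- function(x, ...) {
  cat("Sugeno FIS:", length(x$rules), "rules,",
      length(x$input_names), "inputs (", paste(x$input_names, collapse = ", "), ")\n")
  for (i in seq_along(x$rules)) {
    r <- x$rules[[i]]
    cat(sprintf("  rule %d [%s]: centers (%s), widths (%s)\n", i,
                r$class_tag %||% "?", paste(round(r$center, 3), collapse = ", "),
                paste(round(r$width, 3), collapse = ", ")))
  }
  invisible(x)
}

#' @export
tidy.sugeno_fis <- function(x, ...) {
  purrr::imap_dfr(x$rules, function(r, i) {
    tibble(rule = i, class_tag = r$class_tag %||% NA_character_,
           input = x$input_names, center = r$center, width = r$width)
  })
}

as_input_matrix <- function(fis, x) {
  p <- length(fis$input_names)
  if (is.data.frame(x)) {
    if (all(fis$input_names %in% names(x))) x <- x[fis$input_names]
    x <- as.matrix(x[vapply(x, is.numeric, logical(1))])
  } else if (is.null(dim(x))) {
    if (length(x) != p) abort("Input vector length must equal the input dimension.")
    x <- matrix(x, nrow = 1)
  }
  if (ncol(x) != p) abort("Input dimension mismatch.")
  storage.mode(x) <- "double"
  x
}

#' Firing strength of one rule
#'
#' Product t-norm over the rule's per-input Gaussian membership degrees.
#'
#' @param rule One rule of a [sugeno_fis()].
#' @param x Numeric input vector (length p) or `n x p` matrix.
#' @return Non-negative firing strength(s).
#' @export
rule_firing <- function(rule, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(rule$center)) abort("Input dimension mismatch.")
  w <- rep(1, nrow(x))
  for (j in seq_len(ncol(x))) {
    w <- w * mf_eval(x[, j], rule$center[j], rule$width[j])
  }
  w
}

rule_consequent <- function(rule, x) {
  if (length(rule$coef) == 1L) rep(rule$coef, nrow(x))
  else drop(cbind(1, x) %*% rule$coef)
}

#' Run TSK inference
#'
#' Computes the normalized-weighted-average output
#' `y = sum_i w_i f_i(x) / sum_i w_i`. If every firing strength underflows
#' to zero for a record, the nearest rule's consequent (by scaled distance
#' to the antecedent centers) is used with a warning.
#'
#' @param fis A [sugeno_fis()].
#' @param newdata Input vector, matrix or data frame.
#' @param detail If `TRUE`, also return per-rule firing strengths,
#'   normalized strengths and consequent values (first record only).
#' @return A tibble with column `y_hat`; with `detail = TRUE`, a list with
#'   `y_hat` and a per-rule `detail` tibble.
#' @export
#' @examples
#' fis <- sugeno_fis(
#'   rules = list(
#'     list(center = 0, width = 1, coef = 1, class_tag = "OCD"),
#'     list(center = 4, width = 1, coef = 2, class_tag = "ED")),
#'   input_names = "x", ranges = rbind(0, 4))
#' fis_infer(fis, c(0, 2, 4))
fis_infer <- function(fis, newdata, detail = FALSE) {
  stopifnot(inherits(fis, "sugeno_fis"))
  x <- as_input_matrix(fis, newdata)
  n <- nrow(x); k <- length(fis$rules)
  w <- vapply(fis$rules, rule_firing, numeric(n), x = x)
  w <- matrix(w, nrow = n)
  f <- vapply(fis$rules, rule_consequent, numeric(n), x = x)
  f <- matrix(f, nrow = n)
  wsum <- rowSums(w)
  dead <- wsum <= 0 | !is.finite(wsum)
  if (any(dead)) {
    warn("All firing strengths underflowed for some record(s); using the nearest rule's consequent.")
    centers <- t(vapply(fis$rules, function(r) r$center, numeric(ncol(x))))
    centers <- matrix(centers, nrow = k)
    widths <- t(vapply(fis$rules, function(r) r$width, numeric(ncol(x))))
    widths <- matrix(widths, nrow = k)
    for (i in which(dead)) {
      d <- rowSums(((matrix(x[i, ], k, ncol(x), byrow = TRUE) - centers) / widths)^2)
      w[i, ] <- as.numeric(seq_len(k) == which.min(d))
      wsum[i] <- 1
    }
  }
  wbar <- w / wsum
  y_hat <- rowSums(wbar * f)
  if (detail) {
    list(y_hat = y_hat,
         detail = tibble(rule = seq_len(k), firing = w[1, ],
                         normalized = wbar[1, ], consequent = f[1, ]))
  } else {
    tibble(y_hat = y_hat)
  }
}

#' Seed a Sugeno FIS from a fuzzy c-means fit
#'
#' One rule per cluster: each antecedent membership function is centered at
#' the cluster center's coordinate, with width equal to the
#' membership-weighted standard deviation of the data around the center in
#' that dimension (floored at `width_floor`). Consequents are initialized by
#' a single global least-squares solve of the normalized-firing linear
#' system against the targets; rules carry the majority outcome class of
#' their cluster.
#'
#' @param fit An [fcm_fit()].
#' @param targets Outcome per fitted record (1/2 or "OCD"/"ED"); 1/2 coding
#'   is used as the regression target.
#' @param order `"linear"` (first-order TSK, default) or `"constant"`.
#' @param width_floor Minimum membership-function width.
#' @return A [sugeno_fis()] with one rule per cluster.
#' @export
fis_from_fcm <- function(fit, targets, order = c("linear", "constant"),
                         width_floor = 0.1) {
  stopifnot(inherits(fit, "fcm_fit"))
  order <- match.arg(order)
  data <- fit$data
  p <- ncol(data)
  k <- nrow(fit$centers)
  labels <- as_class_label(targets)
  y <- ifelse(labels == "ED", 2, 1)
  cls <- fcm_classify(fit, labels)
  rules <- vector("list", k)
  for (i in seq_len(k)) {
    u <- fit$membership[, i]
    width <- numeric(p)
    for (j in seq_len(p)) {
      width[j] <- sqrt(sum(u * (data[, j] - fit$centers[i, j])^2) / sum(u))
    }
    rules[[i]] <- list(center = unname(fit$centers[i, ]),
                       width = pmax(width, width_floor),
                       coef = if (order == "linear") rep(0, p + 1) else 0,
                       class_tag = cls$cluster_class[i])
  }
  input_names <- colnames(data) %||% paste0("x", seq_len(p))
  ranges <- apply(data, 2, range)
  fis <- sugeno_fis(rules, input_names, ranges)
  solve_consequents(fis, data, y, order = order)
}

# Global least-squares solve of all rule consequents given fixed premises
# (ANFIS layer-4 linear system). Falls back to a small ridge penalty when
# the system is singular.
solve_consequents <- function(fis, x, y, order = c("linear", "constant"),
                              ridge = 1e-6) {
  order <- match.arg(order)
  x <- as_input_matrix(fis, x)
  n <- nrow(x); k <- length(fis$rules); p <- ncol(x)
  w <- matrix(vapply(fis$rules, rule_firing, numeric(n), x = x), nrow = n)
  wsum <- rowSums(w)
  wsum[wsum <= 0] <- .Machine$double.xmin
  wbar <- w / wsum
  q <- if (order == "linear") p + 1L else 1L
  design <- matrix(0, n, k * q)
  basis <- if (order == "linear") cbind(1, x) else matrix(1, n, 1)
  for (i in seq_len(k)) {
    design[, ((i - 1) * q + 1):(i * q)] <- wbar[, i] * basis
  }
  coefs <- tryCatch(
    qr.coef(qr(design), y),
    error = function(e) rep(NA_real_, k * q)
  )
  if (any(!is.finite(coefs))) {
    warn("Singular consequent system; using ridge-regularized solve.")
    xtx <- crossprod(design) + diag(ridge, k * q)
    coefs <- drop(solve(xtx, crossprod(design, y)))
  }
  for (i in seq_len(k)) {
    fis$rules[[i]]$coef <- unname(coefs[((i - 1) * q + 1):(i * q)])
  }
  fis
}

#' Write a FIS to JSON
#'
#' @param fis A [sugeno_fis()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fis <- function(fis, path) {
  doc <- list(
    input_names = fis$input_names,
    ranges = fis$ranges,
    rules = purrr::map(fis$rules, function(r) {
      list(center = r$center, width = r$width, coef = r$coef,
           class_tag = r$class_tag %||% NA_character_)
    })
  )
  # 17 significant digits round-trips IEEE doubles bit-exactly
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Read a FIS from JSON
#'
#' @param path Path written by [write_fis()].
#' @return A [sugeno_fis()].
#' @export
read_fis <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  rules <- purrr::pmap(doc$rules, function(center, width, coef, class_tag) {
    list(center = unlist(center), width = unlist(width), coef = unlist(coef),
         class_tag = as.character(unlist(class_tag)))
  })
  sugeno_fis(rules, doc$input_names, matrix(doc$ranges, nrow = 2))
}

#' Plot the membership functions of a FIS
#'
#' One panel per input, one Gaussian curve per rule, colored by the rule's
#' outcome class.
#'
#' @param object A [sugeno_fis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sugeno_fis <- function(object, ...) {
  grids <- purrr::imap_dfr(object$input_names, function(nm, j) {
    xs <- seq(object$ranges[1, j], object$ranges[2, j], length.out = 200)
    purrr::imap_dfr(object$rules, function(r, i) {
      tibble(input = nm, x = xs, degree = mf_eval(xs, r$center[j], r$width[j]),
             rule = paste0("rule ", i, " (", r$class_tag %||% "?", ")"))
    })
  })
  ggplot(grids, aes(x = .data$x, y = .data$degree, colour = .data$rule)) +
    geom_line() +
    facet_wrap(~input, scales = "free_x") +
    labs(x = "grouped input value", y = "membership degree", colour = NULL) +
    theme_minimal()
}
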