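# Fuzzy c-means clustering: alternating optimisation of the fuzzy
# within-cluster sum of squares
#   J(U, V) = sum_i sum_k u_ik^m ||x_k - v_i||^2
# with the center update v_i = sum_k u_ik^m x_k / sum_k u_ik^m and the
# membership update u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1)).

as_data_matrix <- function(data) {
  if (is.data.frame(data)) data <- as.matrix(data[vapply(data, is.numeric, logical(1))])
  if (is.null(dim(data))) data <- matrix(data, ncol = 1)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) abort("Data must be finite numeric.")
  data
}

#' Fuzzy c-means objective
#'
#' The membership-weighted within-cluster sum of squared Euclidean
#' distances.
#'
#' @param data Numeric matrix or data frame, records in rows.
#' @param centers `c x p` matrix of cluster centers.
#' @param membership `n x c` matrix of memberships.
#' @param m Fuzzifier exponent (> 1).
#' @return Non-negative scalar.
#' @export
fcm_objective <- function(data, centers, membership, m = 2) {
  data <- as_data_matrix(data)
  centers <- as_data_matrix(centers)
  if (nrow(membership) != nrow(data) || ncol(membership) != nrow(centers) ||
      ncol(data) != ncol(centers)) {
    abort("Shapes of data, centers and membership are inconsistent.")
  }
  d2 <- sq_distances(data, centers)
  sum(membership^m * d2)
}

# n x c matrix of squared Euclidean distances
sq_distances <- function(data, centers) {
  n <- nrow(data); cc <- nrow(centers)
  d2 <- matrix(0, n, cc)
  for (k in seq_len(cc)) {
    d2[, k] <- rowSums(sweep(data, 2, centers[k, ])^2)
  }
  d2
}

#' Fuzzy membership of points given fixed centers
#'
#' Standard FCM membership update. A point coinciding with a center gets
#' membership 1 there (split equally if it coincides with several).
#'
#' @param data Numeric matrix or data frame of points (rows).
#' @param centers `c x p` center matrix.
#' @param m Fuzzifier (> 1).
#' @return `n x c` row-stochastic membership matrix.
#' @export
fcm_membership <- function(data, centers, m = 2) {
  centers <- as_data_matrix(centers)
  # a bare vector of length p is a single point when centers are p-dimensional
  if (is.null(dim(data)) && !is.data.frame(data) &&
      ncol(centers) > 1 && length(data) == ncol(centers)) {
    data <- matrix(data, nrow = 1)
  }
  data <- as_data_matrix(data)
  d2 <- sq_distances(data, centers)
  u <- matrix(0, nrow(d2), ncol(d2))
  zero <- d2 < .Machine$double.eps
  at_center <- rowSums(zero) > 0
  if (any(at_center)) {
    u[at_center, ] <- zero[at_center, , drop = FALSE] /
      rowSums(zero[at_center, , drop = FALSE])
  }
  if (any(!at_center)) {
    r <- d2[!at_center, , drop = FALSE]^(-1 / (m - 1))
    u[!at_center, ] <- r / rowSums(r)
  }
  u
}

#' Fit fuzzy c-means
#'
#' Alternates the center and membership updates from a seeded random
#' row-normalized membership matrix until the maximum absolute membership
#' change falls below `tol` or `max_iter` is reached.
#'
#' @param data Numeric matrix or data frame, one record per row.
#' @param c Number of clusters (>= 2).
#' @param m Fuzzifier exponent (> 1).
#' @param tol Convergence threshold on `max |U_t - U_{t-1}|`.
#' @param max_iter Iteration cap.
#' @param seed Integer seed for the membership initialization.
#' @return An object of class `fcm_fit` with elements `centers`,
#'   `membership`, `objective` (per-iteration trajectory), `iterations`,
#'   `converged` and the data used.
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 8), 10))
#' fit <- fcm_fit(x, c = 2, seed = 1)
#' glance(fit)
fcm_fit <- function(data, c = 2, m = 2, tol = 1e-5, max_iter = 100, seed = 1L) {
  stopifnot(c >= 2, m > 1, tol > 0, max_iter >= 1)
  data <- as_data_matrix(data)
  n <- nrow(data)
  if (n < c) abort("Need at least as many records as clusters.")
  if (nrow(unique(as.data.frame(data))) == 1) {
    warn("All records are identical; cluster centers will coincide.")
  }
  u <- withr::with_seed(seed, {
    u0 <- matrix(runif(n * c), n, c)
    u0 / rowSums(u0)
  })
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0
  centers <- NULL
  for (iter in seq_len(max_iter)) {
    um <- u^m
    centers <- (t(um) %*% data) / colSums(um)
    u_new <- fcm_membership(data, centers, m)
    objective <- c(objective, fcm_objective(data, centers, u_new, m))
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(
    list(centers = centers, membership = u, objective = objective,
         iterations = iter, converged = converged, m = m, data = data),
    class = "fcm_fit"
  )
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat("Fuzzy c-means fit:", nrow(x$centers), "clusters,", nrow(x$data),
      "records,", x$iterations, "iterations",
      if (x$converged) "(converged)\n" else "(iteration cap reached)\n")
  print(round(x$centers, 4))
  invisible(x)
}

#' @export
tidy.fcm_fit <- function(x, ...) {
  centers <- as_tibble(x$centers, .name_repair = "unique_quiet")
  if (is.null(colnames(x$centers))) {
    names(centers) <- paste0("x", seq_len(ncol(x$centers)))
  }
  dplyr::bind_cols(tibble(cluster = seq_len(nrow(x$centers))), centers)
}

#' @export
glance.fcm_fit <- function(x, ...) {
  tibble(n = nrow(x$data), clusters = nrow(x$centers), m = x$m,
         iterations = x$iterations, converged = x$converged,
         objective = tail(x$objective, 1))
}

#' Turn a fuzzy c-means fit into a binary classifier
#'
#' Each cluster is assigned the majority outcome class of its
#' maximum-membership members (ties broken toward extra-prostatic disease);
#' a record's score toward ED is its membership in the ED-assigned cluster.
#'
#' @param fit An [fcm_fit()] object.
#' @param labels Outcome per fitted record: 1/2 or "OCD"/"ED".
#' @return A list with `cluster_class` (per-cluster "OCD"/"ED"), `hard`
#'   (per-record hard cluster), `label` (per-record class) and `ed_score`
#'   (membership in the ED cluster(s)).
#' @export
fcm_classify <- function(fit, labels) {
  stopifnot(inherits(fit, "fcm_fit"))
  labels <- as_class_label(labels)
  if (length(labels) != nrow(fit$membership)) {
    abort("`labels` must match the number of fitted records.")
  }
  hard <- max.col(fit$membership, ties.method = "first")
  k <- nrow(fit$centers)
  cluster_class <- character(k)
  for (i in seq_len(k)) {
    members <- labels[hard == i]
    if (length(members) == 0) abort(paste0("Cluster ", i, " has no members."))
    n_ed <- sum(members == "ED")
    cluster_class[i] <- if (n_ed >= length(members) - n_ed) "ED" else "OCD"
  }
  ed_cols <- which(cluster_class == "ED")
  ed_score <- if (length(ed_cols) == 0) rep(0, nrow(fit$membership)) else
    rowSums(fit$membership[, ed_cols, drop = FALSE])
  list(cluster_class = cluster_class, hard = hard,
       label = cluster_class[hard], ed_score = ed_score)
}

# Coerce 1/2, factor or character labels to "OCD"/"ED"
as_class_label <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    if (any(!x %in% c(1, 2))) abort("Numeric labels must be 1 (OCD) or 2 (ED).")
    return(ifelse(x == 2, "ED", "OCD"))
  }
  if (any(!x %in% c("OCD", "ED"))) abort("Labels must be 'OCD' or 'ED'.")
  x
}
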