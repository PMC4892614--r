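# Independent oracles, written as plain loops so they share no code path
# with the package implementation.

# Brute-force fuzzy c-means objective: literal double sum.
oracle_fcm_objective <- function(data, centers, membership, m) {
  total <- 0
  for (k in seq_len(nrow(data))) {
    for (i in seq_len(nrow(centers))) {
      d2 <- sum((data[k, ] - centers[i, ])^2)
      total <- total + membership[k, i]^m * d2
    }
  }
  total
}

# Brute-force FCM fixed-point iteration run to stagnation from a given
# starting membership matrix.
oracle_fcm_fixed_point <- function(data, u0, m, iters = 2000) {
  u <- u0
  n <- nrow(data); cc <- ncol(u0); p <- ncol(data)
  centers <- matrix(0, cc, p)
  for (it in seq_len(iters)) {
    for (i in seq_len(cc)) {
      num <- rep(0, p); den <- 0
      for (k in seq_len(n)) {
        num <- num + u[k, i]^m * data[k, ]
        den <- den + u[k, i]^m
      }
      centers[i, ] <- num / den
    }
    u_new <- matrix(0, n, cc)
    for (k in seq_len(n)) {
      d <- sqrt(vapply(seq_len(cc), function(i) sum((data[k, ] - centers[i, ])^2),
                       numeric(1)))
      if (any(d == 0)) {
        u_new[k, ] <- as.numeric(d == 0) / sum(d == 0)
      } else {
        for (i in seq_len(cc)) {
          u_new[k, i] <- 1 / sum((d[i] / d)^(2 / (m - 1)))
        }
      }
    }
    if (max(abs(u_new - u)) < 1e-12) { u <- u_new; break }
    u <- u_new
  }
  list(centers = centers, membership = u)
}

# Mann-Whitney AUC with tie correction: pair counting.
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  wins <- 0
  for (a in pos) {
    for (b in neg) {
      wins <- wins + (a > b) + 0.5 * (a == b)
    }
  }
  wins / (length(pos) * length(neg))
}

# A crisp, well-separated two-rule one-input system used in several tests.
toy_two_rule_fis <- function(c1 = 2, c2 = 6, w1 = 1.5, w2 = 1.5,
                             k1 = 1, k2 = 2) {
  sugeno_fis(
    rules = list(
      list(center = c1, width = w1, coef = k1, class_tag = "OCD"),
      list(center = c2, width = w2, coef = k2, class_tag = "ED")
    ),
    input_names = "x", ranges = rbind(0, 8)
  )
}

# Grouped-cohort input column order used throughout.
INPUT_COLS <- c("primary_gleason", "secondary_gleason", "psa_group",
                "age_group", "clinical_t_group")
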