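# AJCC 2010 anatomic stage / prognostic groups for prostate cancer, used as
# the clinical baseline classifier. The grouping table is evaluated row by
# row in printed order; the first matching row wins. "PSA X" / "GS X" rows
# apply only when the respective marker is unknown.

STAGE_LEVELS <- c("I", "IIA", "IIB", "III", "IV")

T_LADDER <- c("T1a", "T1b", "T1c", "T2a", "T2b", "T2c", "T3a", "T3b", "T4")
N_CODES <- c("NX", "N0", "N1")
M_CODES <- c("M0", "M1", "M1a", "M1b", "M1c")

#' Assign the AJCC 2010 anatomic stage group
#'
#' Implements the published grouping table: metastatic disease (any M1) or
#' nodal disease (N1) is stage IV, as is T4; T3a-b is stage III; the
#' organ-confined T categories split into I/IIA/IIB by PSA and Gleason
#' score. Rows requiring "PSA X"/"GS X" match only when the marker is
#' unknown (`NA`).
#'
#' @param t_code Clinical T code(s) (T1a...T4).
#' @param n_code N code(s): NX, N0 or N1 (default N0 — the study dataset
#'   has no nodal column).
#' @param m_code M code(s): M0, M1, M1a-c (default M0).
#' @param psa PSA in ng/mL, or `NA` when unknown.
#' @param gleason_sum Gleason score (primary + secondary pattern, 6-10), or
#'   `NA` when unknown.
#' @return Ordered factor with levels I < IIA < IIB < III < IV.
#' @export
#' @examples
#' anatomic_stage("T1c", psa = 8, gleason_sum = 6)   # I
#' anatomic_stage("T3a", psa = 4, gleason_sum = 9)   # III
anatomic_stage <- function(t_code, n_code = "N0", m_code = "M0",
                           psa = NA_real_, gleason_sum = NA_real_) {
  n_rec <- max(length(t_code), length(n_code), length(m_code),
               length(psa), length(gleason_sum))
  t_code <- rep_len(as.character(t_code), n_rec)
  n_code <- rep_len(as.character(n_code), n_rec)
  m_code <- rep_len(as.character(m_code), n_rec)
  psa <- rep_len(as.numeric(psa), n_rec)
  gs <- rep_len(as.numeric(gleason_sum), n_rec)
  bad_t <- !t_code %in% c(T_LADDER, "TX", "T0")
  if (any(bad_t)) abort(paste0("Unknown T code(s): ",
                               paste(unique(t_code[bad_t]), collapse = ", ")),
                        class = "fuzzystage_vocabulary_error")
  if (any(!n_code %in% N_CODES)) abort("N codes must be NX, N0 or N1.",
                                       class = "fuzzystage_vocabulary_error")
  if (any(!m_code %in% M_CODES)) abort("M codes must be M0 or M1/M1a-c.",
                                       class = "fuzzystage_vocabulary_error")
  if (any(!is.na(psa) & psa <= 0)) abort("Known PSA must be positive.",
                                         class = "fuzzystage_invalid_value")

  out <- character(n_rec)
  t1ac <- t_code %in% c("T1a", "T1b", "T1c")
  t12a <- t_code %in% c("T1a", "T1b", "T1c", "T2a")
  t12 <- t_code %in% c("T1a", "T1b", "T1c", "T2a", "T2b", "T2c")
  m1 <- m_code != "M0"
  n1 <- n_code == "N1"
  base_ok <- n_code == "N0" & !m1

  for (i in seq_len(n_rec)) {
    row <- NA_character_
    if (m1[i]) row <- "IV"
    else if (n1[i]) row <- "IV"
    else if (base_ok[i]) {
      psa_i <- psa[i]; gs_i <- gs[i]
      known <- !is.na(psa_i) && !is.na(gs_i)
      if (t1ac[i] && known && psa_i < 10 && gs_i <= 6) row <- "I"
      else if (t_code[i] == "T2a" && known && psa_i < 10 && gs_i <= 6) row <- "I"
      else if (t12a[i] && is.na(psa_i) && is.na(gs_i)) row <- "I"
      else if (t1ac[i] && known && psa_i < 20 && gs_i == 7) row <- "IIA"
      else if (t1ac[i] && known && psa_i >= 10 && psa_i < 20 && gs_i <= 6) row <- "IIA"
      else if (t_code[i] == "T2a" && known && psa_i < 20 && gs_i <= 7) row <- "IIA"
      else if (t_code[i] == "T2b" && known && psa_i < 20 && gs_i <= 7) row <- "IIA"
      else if (t_code[i] == "T2b" && is.na(psa_i) && is.na(gs_i)) row <- "IIA"
      else if (t_code[i] == "T2c") row <- "IIB"
      else if (t12[i] && !is.na(psa_i) && psa_i >= 20) row <- "IIB"
      else if (t12[i] && !is.na(gs_i) && gs_i >= 8) row <- "IIB"
      else if (t_code[i] %in% c("T3a", "T3b")) row <- "III"
      else if (t_code[i] == "T4") row <- "IV"
    }
    if (is.na(row)) {
      abort(paste0("Record ", i, " (", t_code[i], " ", n_code[i], " ", m_code[i],
                   ") matches no stage-group row."),
            class = "fuzzystage_unstageable")
    }
    out[i] <- row
  }
  factor(out, levels = STAGE_LEVELS, ordered = TRUE)
}

#' Reduce an anatomic stage group to the binary outcome
#'
#' Stages I and II are organ-confined; stages III and IV are
#' extra-prostatic.
#'
#' @param group Stage group(s) from [anatomic_stage()].
#' @return Character vector of "OCD"/"ED".
#' @export
binary_stage <- function(group) {
  group <- as.character(group)
  if (any(!group %in% STAGE_LEVELS)) abort("Unknown stage group.")
  ifelse(group %in% c("III", "IV"), "ED", "OCD")
}

#' Ordinal nomogram score
#'
#' The stage group's rank (I = 1 ... IV = 5), used to place the nomogram on
#' a ROC curve as a five-level classifier.
#'
#' @inheritParams anatomic_stage
#' @return Integer scores in 1..5.
#' @export
nomogram_score <- function(t_code, n_code = "N0", m_code = "M0",
                           psa = NA_real_, gleason_sum = NA_real_) {
  as.integer(anatomic_stage(t_code, n_code, m_code, psa, gleason_sum))
}
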