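#' Per-shell Welch comparison of two cohorts
#'
#' For each shell, an unpaired, unequal-variance (Welch), two-tailed t-test on
#' the per-nucleus normalized values of the two cohorts, with
#' Welch-Satterthwaite degrees of freedom. No multiple-testing correction is
#' applied across shells: each shell is tested at `alpha` on its own, matching
#' the per-shell significance convention of erosion-analysis figures.
#'
#' @param a,b `cohort_profile` objects with the same number of shells.
#' @param alpha Per-shell significance level (default 0.05).
#' @param measure Column of the per-nucleus data to test: `"normalized"` (the
#'   probe profile) or `"raw_dapi_pct"` (the DAPI control).
#'
#' @return A tibble with one row per shell: `shell`, `t_stat`, `df`,
#'   `p_value`, `significant`.
#' @export
compare_cohorts <- function(a, b, alpha = 0.05, measure = "normalized") {
  stopifnot(inherits(a, "cohort_profile"), inherits(b, "cohort_profile"))
  if (a$n_shells != b$n_shells) {
    stop_rf("shape", "cohorts have different shell counts")
  }
  if (a$n < 2L || b$n < 2L) stop_rf("sample_size", "each cohort needs n >= 2")
  if (!measure %in% names(a$data) || !measure %in% names(b$data)) {
    stop_rf("value", sprintf("per-nucleus column '%s' not retained in both cohorts", measure))
  }
  purrr::map_dfr(seq_len(a$n_shells), function(k) {
    xa <- a$data[[measure]][a$data$shell == k]
    xb <- b$data[[measure]][b$data$shell == k]
    welch_row(xa, xb, alpha) |> dplyr::mutate(shell = k, .before = 1L)
  })
}

#' DAPI-distribution control between two cohorts
#'
#' Applies the same per-shell Welch test to the raw DAPI percentages instead
#' of the probe signal. A treatment that repositions a chromosome should leave
#' this control non-significant in every shell: the DNA distribution over
#' shells is not expected to change.
#'
#' @inheritParams compare_cohorts
#' @return As [compare_cohorts()].
#' @export
dapi_control <- function(a, b, alpha = 0.05) {
  compare_cohorts(a, b, alpha = alpha, measure = "raw_dapi_pct")
}

#' Classify the radial position of a cohort profile
#'
#' Reduces the mean normalized profile to its center of mass over shell
#' indices, `com = sum(k * m_k) / sum(m_k)`, and thresholds it into the
#' peripheral / intermediate / interior vocabulary: `P` if `com <
#' thresholds[1]`, `I` if `com > thresholds[2]`, `IM` between (inclusive).
#' The index is invariant to uniform scaling of the profile. The thresholds
#' are this package's operational definition of the three codes; the
#' measurement itself (the profile) carries the full information.
#'
#' @param x A `cohort_profile`, or a numeric vector giving a mean normalized
#'   profile (shell 1 first).
#' @param thresholds Length-2 increasing vector of center-of-mass cut points,
#'   default `c(2.75, 3.25)` for 5 shells.
#'
#' @return A one-row tibble: `com_index`, `position` (`"P"`, `"IM"`, `"I"`).
#' @export
classify_position <- function(x, thresholds = c(2.75, 3.25)) {
  stopifnot(length(thresholds) == 2L, diff(thresholds) >= 0)
  m <- if (inherits(x, "cohort_profile")) tidy(x)$mean else as.numeric(x)
  if (any(m < 0) || sum(m) <= 0) {
    stop_rf("degenerate_profile", "mean profile must be non-negative with positive sum")
  }
  k <- seq_along(m)
  com <- sum(k * m) / sum(m)
  position <- if (com < thresholds[1L]) "P" else if (com > thresholds[2L]) "I" else "IM"
  tibble(com_index = com, position = position)
}
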