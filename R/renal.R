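#' Estimated GFR from serum creatinine (Japanese equation)
#'
#' `eGFR = 194 * Cr^-1.094 * age^-0.287`, multiplied by 0.739 for women;
#' units mL/min/1.73 m^2. Strictly decreasing in creatinine and in age.
#'
#' @param creatinine Serum creatinine, mg/dL (> 0).
#' @param age Age in years (> 0).
#' @param sex `"male"` or `"female"`.
#' @return Numeric eGFR.
#' @examples
#' egfr_japanese(1.0, 50, "male") # ~63.1
#' @export
egfr_japanese <- function(creatinine, age, sex) {
  if (any(creatinine <= 0, na.rm = TRUE) || any(age <= 0, na.rm = TRUE)) {
    stop("`creatinine` and `age` must be positive", call. = FALSE)
  }
  bad <- !is.na(sex) & !sex %in% c("male", "female")
  if (any(bad)) stop("`sex` must be \"male\" or \"female\"", call. = FALSE)
  194 * creatinine^(-1.094) * age^(-0.287) *
    ifelse(sex == "female", 0.739, 1)
}

#' Classify the five-year kidney outcome
#'
#' Worsening kidney function is a >= 30% decrease in eGFR from baseline at
#' any follow-up within the window, i.e. any follow-up eGFR at or below
#' 70% of baseline; in worker cohorts an ESKD-type event (end-stage kidney
#' disease diagnosis, maintenance dialysis initiation, kidney transplant)
#' also qualifies. Stable kidney function is its complement.
#'
#' @param baseline_egfr Baseline eGFR.
#' @param followup_egfr Vector of in-window follow-up eGFR values (at
#'   least one required).
#' @param eskd_event Any ESKD-type event in the window?
#' @param cohort_kind `"general"` or `"worker"`; ESKD events only count
#'   for worker cohorts.
#' @return A list: `outcome` (`"stable"` or `"worsening"`) and
#'   `worst_pct_change` (minimum signed percent change from baseline).
#' @examples
#' classify_outcome(80, c(75, 70, 55))$outcome # worsening (-31.25%)
#' classify_outcome(80, c(75, 70, 60))$outcome # stable (-25%)
#' @export
classify_outcome <- function(baseline_egfr, followup_egfr,
                             eskd_event = FALSE,
                             cohort_kind = c("general", "worker")) {
  cohort_kind <- match.arg(cohort_kind)
  if (length(followup_egfr) == 0L || all(is.na(followup_egfr))) {
    stop("no follow-up eGFR available; subject should have been excluded ",
         "during assembly", call. = FALSE)
  }
  worst <- min(100 * (followup_egfr / baseline_egfr - 1), na.rm = TRUE)
  worsening <- worst <= -30 ||
    (cohort_kind == "worker" && isTRUE(any(eskd_event)))
  list(outcome = if (worsening) "worsening" else "stable",
       worst_pct_change = worst)
}

#' Two-year eGFR change and its stratum
#'
#' `two_year_change()` picks the follow-up eGFR nearest to baseline + 2
#' years (within +-1 year, ties broken toward the earlier visit) and
#' returns the signed percent change from baseline, or `NA` when no visit
#' falls in the window. `slope_stratum()` bins a percent change:
#' `>= 0` is `"ge0"`, `[-30, 0)` is `"minus30to0"`, `< -30` is
#' `"lt_minus30"`, `NA` is `"missing"`.
#'
#' @param years Follow-up visit years.
#' @param egfr Follow-up eGFR values, parallel to `years`.
#' @param baseline_year,baseline_egfr Baseline visit year and eGFR.
#' @return `two_year_change()`: one percent change (possibly `NA`);
#'   `slope_stratum()`: character vector of stratum labels.
#' @export
two_year_change <- function(years, egfr, baseline_year, baseline_egfr) {
  d <- years - baseline_year
  ok <- which(!is.na(egfr) & d >= 1 & d <= 3)
  if (!length(ok)) return(NA_real_)
  i <- ok[order(abs(d[ok] - 2), d[ok])][1]
  100 * (egfr[i] / baseline_egfr - 1)
}

#' @rdname two_year_change
#' @param pct_change Signed percent change (may be `NA`).
#' @export
slope_stratum <- function(pct_change) {
  dplyr::case_when(
    is.na(pct_change) ~ "missing",
    pct_change >= 0 ~ "ge0",
    pct_change >= -30 ~ "minus30to0",
    TRUE ~ "lt_minus30"
  )
}

#' Baseline rows of an assembled cohort
#'
#' One row per subject at the baseline visit, with the computed `egfr`
#' column appended.
#'
#' @param cohort A `dkd_cohort`.
#' @return A tibble, one row per subject.
#' @export
baseline_rows <- function(cohort) {
  stopifnot(inherits(cohort, "dkd_cohort"))
  cohort$visits |>
    dplyr::inner_join(cohort$baselines, by = "subject_id") |>
    dplyr::filter(.data$year == .data$baseline_year) |>
    dplyr::select(-"baseline_year") |>
    dplyr::mutate(egfr = egfr_japanese(.data$serum_creatinine, .data$age,
                                       .data$sex))
}

#' Per-subject renal outcomes
#'
#' Computes, for every subject in an assembled cohort, the baseline eGFR,
#' the worst (most negative) percent change over in-window follow-ups, the
#' stable/worsening outcome, the two-year eGFR change and its stratum.
#'
#' @param cohort A `dkd_cohort`.
#' @return A tibble with columns `subject_id`, `baseline_egfr`,
#'   `worst_pct_change`, `outcome`, `egfr_2y_change_pct`, `slope_stratum`.
#' @export
renal_outcomes <- function(cohort) {
  stopifnot(inherits(cohort, "dkd_cohort"))
  base <- baseline_rows(cohort) |>
    dplyr::select("subject_id", baseline_egfr = "egfr",
                  baseline_age = "age")
  worker <- cohort$cohort_kind == "worker"

  fu <- cohort$visits |>
    dplyr::inner_join(cohort$baselines, by = "subject_id") |>
    dplyr::filter(.data$year > .data$baseline_year,
                  !is.na(.data$serum_creatinine)) |>
    dplyr::mutate(egfr = egfr_japanese(.data$serum_creatinine, .data$age,
                                       .data$sex)) |>
    dplyr::inner_join(base, by = "subject_id")

  out <- fu |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      baseline_egfr = .data$baseline_egfr[1],
      worst_pct_change = min(100 * (.data$egfr / .data$baseline_egfr - 1)),
      eskd = worker && any(.data$eskd_event %in% TRUE),
      egfr_2y_change_pct = two_year_change(.data$year, .data$egfr,
                                           .data$baseline_year[1],
                                           .data$baseline_egfr[1]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      outcome = dplyr::if_else(.data$worst_pct_change <= -30 | .data$eskd,
                               "worsening", "stable"),
      slope_stratum = slope_stratum(.data$egfr_2y_change_pct)
    ) |>
    dplyr::select("subject_id", "baseline_egfr", "worst_pct_change",
                  "outcome", "egfr_2y_change_pct", "slope_stratum")
  out
}
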