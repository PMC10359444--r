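#' Diabetes status from examination values
#'
#' A visit meets the diabetes definition when HbA1c >= 6.5%, fasting
#' plasma glucose >= 7.0 mmol/L (126 mg/dL), or the subject is on diabetes
#' treatment. Missing criteria are treated as not met; if all three fields
#' are missing the status is indeterminate and an error is raised.
#'
#' @param hba1c HbA1c in percent (may be `NA`).
#' @param fasting_glucose Fasting plasma glucose in mmol/L (may be `NA`).
#' @param on_dm_treatment Logical treatment flag (may be `NA`).
#' @return Logical vector.
#' @examples
#' is_diabetic(6.5, 5.0, FALSE) # TRUE, at the HbA1c boundary
#' is_diabetic(6.4, 6.9, FALSE) # FALSE
#' @export
is_diabetic <- function(hba1c, fasting_glucose, on_dm_treatment) {
  all_missing <- is.na(hba1c) & is.na(fasting_glucose) & is.na(on_dm_treatment)
  if (any(all_missing)) {
    stop("diabetes status indeterminate: HbA1c, fasting glucose and ",
         "treatment flag all missing (element ", which(all_missing)[1], ")",
         call. = FALSE)
  }
  (!is.na(hba1c) & hba1c >= 6.5) |
    (!is.na(fasting_glucose) & fasting_glucose >= 7.0) |
    (!is.na(on_dm_treatment) & on_dm_treatment)
}

#' Baseline visit selection
#'
#' Baseline is the earliest creatinine-bearing visit from which the
#' subject is still followed for at least `followup_years` (span from
#' baseline to last recorded visit) and has at least one later visit.
#' Subjects with no qualifying visit get `NA`.
#'
#' @param visits Visit records for one or more subjects.
#' @param followup_years Required span in years (default 5).
#' @return A tibble with one row per subject: `subject_id`,
#'   `baseline_year` (`NA` when unset).
#' @export
select_baseline <- function(visits, followup_years = 5) {
  visits |>
    dplyr::arrange(.data$subject_id, .data$year) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      baseline_year = {
        cr_years <- .data$year[!is.na(.data$serum_creatinine)]
        last <- if (length(.data$year)) max(.data$year) else NA_integer_
        ok <- cr_years[last - cr_years >= followup_years & cr_years < last]
        if (length(ok)) min(ok) else NA_integer_
      },
      .groups = "drop"
    )
}

#' Assemble an analysis cohort from raw visit records
#'
#' Applies the eligibility cascade: subjects must meet the diabetes
#' definition at baseline (falling back to the most recent earlier visit
#' when the baseline labs are missing), have a baseline eGFR measurement
#' (a creatinine-bearing visit qualifying under [select_baseline()]), and
#' have at least one creatinine-bearing follow-up visit within
#' `followup_years` after baseline. Each excluded subject is assigned the
#' first failing reason in the order `not_diabetic`, `no_baseline_egfr`,
#' `insufficient_followup`.
#'
#' Visits after the follow-up window are dropped from the assembled
#' cohort; re-running `assemble_cohort()` on its own visits is a no-op.
#'
#' @param visits Visit records (validated against [cohort_schema()]).
#' @param cohort_kind `"general"` or `"worker"` (worker cohorts count
#'   ESKD-type events as worsening downstream).
#' @param followup_years Outcome window length in years (default 5).
#' @return An object of class `dkd_cohort`: a list with `visits` (eligible
#'   subjects, windowed to `[baseline, baseline + followup_years]`),
#'   `baselines`, `report` (eligibility counts and per-subject exclusion
#'   reasons), `cohort_kind` and `followup_years`.
#' @examples
#' v <- simulate_cohort(cohort_profile(n_subjects = 200, seed = 2))
#' coh <- assemble_cohort(v)
#' glance(coh)
#' @export
assemble_cohort <- function(visits, cohort_kind = c("general", "worker"),
                            followup_years = 5) {
  cohort_kind <- match.arg(cohort_kind)
  latent <- attr(visits, "latent")
  visits <- validate_cohort(visits)
  visits <- dplyr::arrange(visits, .data$subject_id, .data$year)

  if (nrow(visits) == 0L) {
    report <- list(
      counts = tibble::tibble(n_input_subjects = 0L, n_diabetes = 0L,
                              n_with_baseline = 0L, n_followed = 0L,
                              n_final = 0L),
      exclusions = tibble::tibble(subject_id = character(),
                                  reason = character())
    )
    return(new_dkd_cohort(visits, select_baseline(visits)[0, ], report,
                          cohort_kind, followup_years, latent))
  }

  base <- select_baseline(visits, followup_years)

  per <- visits |>
    dplyr::left_join(base, by = "subject_id") |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      baseline_year = .data$baseline_year[1],
      any_creatinine = any(!is.na(.data$serum_creatinine)),
      has_followup = !is.na(.data$baseline_year[1]) &&
        any(!is.na(.data$serum_creatinine) &
              .data$year > .data$baseline_year[1] &
              .data$year <= .data$baseline_year[1] + followup_years),
      diabetic = {
        anchor <- if (is.na(.data$baseline_year[1])) min(.data$year)
                  else .data$baseline_year[1]
        informative <- .data$year <= anchor &
          (!is.na(.data$hba1c) | !is.na(.data$fasting_glucose) |
             !is.na(.data$on_dm_treatment))
        if (!any(informative)) FALSE else {
          i <- max(which(informative)) # latest visit at/before the anchor
          is_diabetic(.data$hba1c[i], .data$fasting_glucose[i],
                      .data$on_dm_treatment[i])
        }
      },
      .groups = "drop"
    )

  per$eligible <- per$diabetic & !is.na(per$baseline_year) & per$has_followup
  per$reason <- dplyr::case_when(
    per$eligible ~ NA_character_,
    !per$diabetic ~ "not_diabetic",
    !per$any_creatinine ~ "no_baseline_egfr",
    TRUE ~ "insufficient_followup"
  )

  report <- list(
    counts = tibble::tibble(
      n_input_subjects = nrow(per),
      n_diabetes = sum(per$diabetic),
      n_with_baseline = sum(per$diabetic & !is.na(per$baseline_year)),
      n_followed = sum(per$eligible),
      n_final = sum(per$eligible)
    ),
    exclusions = per |>
      dplyr::filter(!is.na(.data$reason)) |>
      dplyr::select("subject_id", "reason")
  )

  keep <- per |>
    dplyr::filter(.data$eligible) |>
    dplyr::select("subject_id", "baseline_year")
  windowed <- visits |>
    dplyr::inner_join(keep, by = "subject_id") |>
    dplyr::filter(.data$year >= .data$baseline_year,
                  .data$year <= .data$baseline_year + followup_years) |>
    dplyr::select(-"baseline_year")

  new_dkd_cohort(windowed, keep, report, cohort_kind, followup_years, latent)
}

new_dkd_cohort <- function(visits, baselines, report, cohort_kind,
                           followup_years, latent = NULL) {
  structure(
    list(visits = visits, baselines = baselines, report = report,
         cohort_kind = cohort_kind, followup_years = followup_years),
    latent = latent,
    class = "dkd_cohort"
  )
}

#' @export
print.dkd_cohort <- function(x, ...) {
  cnt <- x$report$counts
  cat("<dkd_cohort> ", x$cohort_kind, " cohort, follow-up ",
      x$followup_years, " y\n", sep = "")
  cat("  subjects: ", cnt$n_input_subjects, " in -> ", cnt$n_diabetes,
      " diabetic -> ", cnt$n_with_baseline, " with baseline eGFR -> ",
      cnt$n_final, " analysed\n", sep = "")
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row eligibility summary of an assembled cohort
#' @param x A `dkd_cohort`.
#' @param ... Unused.
#' @export
glance.dkd_cohort <- function(x, ...) {
  x$report$counts
}

#' Per-subject exclusion reasons of an assembled cohort
#' @param x A `dkd_cohort`.
#' @param ... Unused.
#' @export
tidy.dkd_cohort <- function(x, ...) {
  x$report$exclusions
}
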