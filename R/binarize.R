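#' Risk-factor specifications
#'
#' The 17 factors assessed at baseline. Continuous factors are flagged by
#' sex-specific percentile thresholds: for `high_is_risk` factors the
#' upper tail is risk (HbA1c, fasting glucose, AST, ALT, GGT, total
#' cholesterol, triglyceride, LDL, systolic and diastolic blood pressure,
#' BMI); for `low_is_risk` factors the lower tail (eGFR, hemoglobin —
#' anemia — and HDL). Categorical factors: urine protein (dipstick >= 1+
#' is risk), diabetic retinopathy (present is risk; used as a stratifier
#' by default) and the two-year eGFR decrease (stratifier only). The
#' `role` column says whether a factor enters rules or only defines
#' strata.
#'
#' Direction assignments for the continuous factors are package defaults
#' reconstructed from standard clinical reasoning about each analyte; the
#' tail size is the `percentile` argument of [compute_thresholds()].
#'
#' @param percentile Tail size in percent, 20 (default) or 10 (the
#'   sensitivity setting).
#' @param include_retinopathy Also use retinopathy as a rule factor
#'   (default `FALSE`: stratifier only).
#' @return A tibble with columns `factor`, `source_field`, `direction`,
#'   `percentile`, `categorical_rule`, `role`.
#' @export
risk_factor_specs <- function(percentile = 20, include_retinopathy = FALSE) {
  if (!percentile %in% c(10, 20)) {
    stop("`percentile` must be 10 or 20", call. = FALSE)
  }
  high <- c("hba1c", "fasting_glucose", "ast", "alt", "ggt", "total_chol",
            "triglyceride", "ldl", "sbp", "dbp", "bmi")
  low <- c("egfr", "hemoglobin", "hdl")
  cont <- tibble::tibble(
    factor = c("egfr", "hba1c", "fasting_glucose", "hemoglobin", "ast",
               "alt", "ggt", "total_chol", "triglyceride", "hdl", "ldl",
               "sbp", "dbp", "bmi")
  ) |>
    dplyr::mutate(
      source_field = .data$factor,
      direction = dplyr::if_else(.data$factor %in% low, "low_is_risk",
                                 "high_is_risk"),
      percentile = percentile,
      categorical_rule = NA_character_,
      role = "rule"
    )
  cat_ <- tibble::tibble(
    factor = c("urine_protein", "retinopathy", "egfr_2y_change"),
    source_field = c("dipstick_protein", "retinopathy", "egfr_2y_change_pct"),
    direction = "categorical",
    percentile = NA_real_,
    categorical_rule = c("dipstick >= 1+", "present", "slope stratum"),
    role = c("rule",
             if (include_retinopathy) "rule" else "stratifier",
             "stratifier")
  )
  dplyr::bind_rows(
    cont[cont$factor == "egfr", ],
    cat_[cat_$factor == "urine_protein", ],
    cont[cont$factor != "egfr", ],
    cat_[cat_$factor != "urine_protein", ]
  )
}

rule_factors <- function(specs) specs$factor[specs$role == "rule"]

#' Sex-specific percentile thresholds for continuous risk factors
#'
#' For each continuous factor and sex, the threshold is the
#' `(100 - percentile)`-th percentile of non-missing baseline values for
#' `high_is_risk` factors and the `percentile`-th percentile for
#' `low_is_risk` factors, estimated with linear interpolation between
#' order statistics (`stats::quantile()` type 7). Thresholds are computed
#' on the whole analysis cohort by sex, before any stratification.
#'
#' @param baseline Baseline rows (see [baseline_rows()]); must contain a
#'   `sex` column and each factor's source field.
#' @param specs Factor specifications from [risk_factor_specs()].
#' @param percentile Tail size in percent; defaults to the value carried
#'   in `specs`.
#' @return A tibble with columns `factor`, `sex`, `direction`,
#'   `percentile`, `threshold`.
#' @export
compute_thresholds <- function(baseline, specs = risk_factor_specs(),
                               percentile = NULL) {
  cont <- specs[specs$direction != "categorical", ]
  if (!is.null(percentile)) cont$percentile <- percentile
  sexes <- sort(unique(baseline$sex))
  grid <- tidyr::expand_grid(
    cont[, c("factor", "source_field", "direction", "percentile")],
    sex = sexes
  )
  grid$threshold <- purrr::pmap_dbl(
    grid,
    function(factor, source_field, direction, percentile, sex) {
      x <- baseline[[source_field]][baseline$sex == sex]
      x <- x[!is.na(x)]
      if (!length(x)) {
        stop("no non-missing baseline values for factor `", factor,
             "`, sex `", sex, "`", call. = FALSE)
      }
      p <- if (direction == "high_is_risk") 1 - percentile / 100
           else percentile / 100
      stats::quantile(x, p, type = 7, names = FALSE)
    }
  )
  grid[, c("factor", "sex", "direction", "percentile", "threshold")]
}

#' Binarize baseline risk factors against thresholds
#'
#' Presence of a continuous factor requires strict exceedance: value
#' strictly above the threshold for `high_is_risk` factors, strictly
#' below for `low_is_risk`; a value exactly at the threshold is absent.
#' Categorical factors use their rule (dipstick >= 1+; retinopathy
#' present). A missing analyte yields a missing flag for that factor
#' only.
#'
#' @param baseline Baseline rows with an `egfr` column (see
#'   [baseline_rows()]).
#' @param thresholds Output of [compute_thresholds()].
#' @param specs Factor specifications.
#' @return A tibble: `subject_id`, `sex`, and one logical `risk_<factor>`
#'   column per rule factor.
#' @export
binarize_risk_factors <- function(baseline, thresholds,
                                  specs = risk_factor_specs()) {
  out <- baseline[, c("subject_id", "sex")]
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    if (sp$role != "rule") next
    col <- paste0("risk_", sp$factor)
    if (sp$direction == "categorical") {
      if (sp$factor == "urine_protein") {
        out[[col]] <- baseline$dipstick_protein %in% c("1+", "2+", "3+") |
          dplyr::if_else(is.na(baseline$dipstick_protein), NA, FALSE)
      } else if (sp$factor == "retinopathy") {
        out[[col]] <- baseline$retinopathy
      }
      next
    }
    thr <- thresholds[thresholds$factor == sp$factor, ]
    t_by_sex <- unname(stats::setNames(thr$threshold, thr$sex)[baseline$sex])
    v <- baseline[[sp$source_field]]
    out[[col]] <- if (sp$direction == "high_is_risk") v > t_by_sex
                  else v < t_by_sex
  }
  out
}

#' Build the per-subject exposure-outcome table
#'
#' Joins baseline risk-factor flags, the renal outcome, and the
#' stratification labels (modified KDIGO risk category, retinopathy,
#' two-year slope stratum) into one row per analysed subject. Thresholds
#' are computed within the cohort at baseline, by sex.
#'
#' @param cohort A `dkd_cohort` from [assemble_cohort()].
#' @param percentile Tail size in percent, 20 (default) or 10.
#' @param specs Factor specifications; defaults to
#'   `risk_factor_specs(percentile)`.
#' @param risk_map Risk-category grid, see [ckd_risk_map()].
#' @return A tibble of class `dkd_exposure` with attributes `specs`,
#'   `thresholds`, `cohort_kind` and `percentile`.
#' @examples
#' v <- simulate_cohort(cohort_profile(n_subjects = 300, seed = 3))
#' ex <- build_exposure_table(assemble_cohort(v))
#' dplyr::count(ex, risk_category, outcome)
#' @export
build_exposure_table <- function(cohort, percentile = 20,
                                 specs = risk_factor_specs(percentile),
                                 risk_map = ckd_risk_map()) {
  base <- baseline_rows(cohort)
  outc <- renal_outcomes(cohort)
  thr <- compute_thresholds(base, specs)
  flags <- binarize_risk_factors(base, thr, specs)

  staged <- base |>
    dplyr::transmute(
      .data$subject_id,
      gfr_grade = gfr_grade(.data$egfr),
      proteinuria_class = dplyr::if_else(
        .data$dipstick_protein %in% c("1+", "2+", "3+"),
        "ge1plus", "neg_trace"
      ),
      retinopathy = .data$retinopathy
    ) |>
    dplyr::mutate(
      risk_category = risk_category(.data$gfr_grade,
                                    .data$proteinuria_class, risk_map)
    )

  out <- flags |>
    dplyr::inner_join(staged, by = "subject_id") |>
    dplyr::inner_join(outc, by = "subject_id")
  structure(out,
            specs = specs, thresholds = thr,
            cohort_kind = cohort$cohort_kind, percentile = percentile,
            class = c("dkd_exposure", class(out)))
}
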