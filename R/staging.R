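#' GFR grade (KDIGO G1-G5)
#'
#' Half-open bins, lower bound inclusive: `[90, Inf)` G1, `[60, 90)` G2,
#' `[45, 60)` G3a, `[30, 45)` G3b, `[15, 30)` G4, `(0, 15)` G5.
#'
#' @param egfr eGFR in mL/min/1.73 m^2 (> 0).
#' @return Character vector of grades.
#' @examples
#' gfr_grade(c(90, 60, 59.99, 44.9, 14))
#' @export
gfr_grade <- function(egfr) {
  if (any(egfr <= 0, na.rm = TRUE)) {
    stop("`egfr` must be positive", call. = FALSE)
  }
  labels <- c("G5", "G4", "G3b", "G3a", "G2", "G1")
  i <- findInterval(egfr, c(15, 30, 45, 60, 90)) + 1L
  out <- labels[i]
  out[is.na(egfr)] <- NA_character_
  out
}

gfr_grade_levels <- function() c("G1", "G2", "G3a", "G3b", "G4", "G5")
risk_category_levels <- function() c("low", "moderate", "high", "very_high")

#' Modified KDIGO risk-category grid
#'
#' The CKD risk-category heat map with albuminuria replaced by dipstick
#' proteinuria dichotomized as negative/trace vs >= 1+. The default maps
#' the negative/trace column like the KDIGO A1 column (G1/G2 low, G3a
#' moderate, G3b high, G4/G5 very high) and the >= 1+ column like A2
#' (G1/G2 moderate, G3a high, G3b-G5 very high). This two-column
#' collapse is a package assumption (the three-level KDIGO albuminuria
#' axis does not exist in dipstick data); supply your own grid to
#' override.
#'
#' @return A tibble with columns `gfr_grade`, `proteinuria_class`,
#'   `category`.
#' @export
ckd_risk_map <- function() {
  tibble::tibble(
    gfr_grade = rep(gfr_grade_levels(), 2),
    proteinuria_class = rep(c("neg_trace", "ge1plus"), each = 6),
    category = c("low", "low", "moderate", "high", "very_high", "very_high",
                 "moderate", "moderate", "high", "very_high", "very_high",
                 "very_high")
  )
}

#' Risk category from GFR grade and proteinuria class
#'
#' @param gfr_grade Character vector of grades (see [gfr_grade()]).
#' @param proteinuria_class `"neg_trace"` or `"ge1plus"`.
#' @param map Category grid, by default [ckd_risk_map()].
#' @return Character vector of categories: `low`, `moderate`, `high`,
#'   `very_high`.
#' @examples
#' risk_category("G1", "neg_trace") # low
#' risk_category("G3a", "neg_trace") # moderate
#' @export
risk_category <- function(gfr_grade, proteinuria_class,
                          map = ckd_risk_map()) {
  key <- paste(gfr_grade, proteinuria_class)
  lut <- stats::setNames(map$category,
                         paste(map$gfr_grade, map$proteinuria_class))
  bad <- !is.na(key) & !key %in% names(lut) &
    !(is.na(gfr_grade) | is.na(proteinuria_class))
  if (any(bad)) {
    stop("no risk-category mapping for: ", key[bad][1], call. = FALSE)
  }
  unname(lut[key])
}

#' Stratification schemes
#'
#' `assign_strata()` labels each exposure row under a scheme:
#' * `overall` — a single stratum `"all"`;
#' * `risk4` — the four risk categories;
#' * `risk2_retinopathy` — low/moderate vs high/very-high crossed with
#'   retinopathy status;
#' * `risk2_retinopathy_slope` — additionally crossed with the two-year
#'   eGFR-change stratum.
#'
#' Rows with a missing label component (unknown retinopathy, no two-year
#' measurement) get `NA` and are dropped from that scheme only.
#' `stratum_levels()` enumerates the scheme's strata in canonical order,
#' including strata that happen to be empty.
#'
#' @param exposure A `dkd_exposure` table.
#' @param scheme Scheme name.
#' @return `assign_strata()`: character vector of stratum labels (`NA` =
#'   unassigned); `stratum_levels()`: character vector of levels.
#' @export
assign_strata <- function(exposure,
                          scheme = c("overall", "risk4",
                                     "risk2_retinopathy",
                                     "risk2_retinopathy_slope")) {
  scheme <- match.arg(scheme)
  if (scheme == "overall") return(rep("all", nrow(exposure)))
  if (scheme == "risk4") return(exposure$risk_category)
  risk2 <- dplyr::if_else(exposure$risk_category %in% c("low", "moderate"),
                          "low_moderate", "high_veryhigh")
  ret <- dplyr::if_else(exposure$retinopathy, "retinopathy",
                        "no_retinopathy")
  lab <- paste(risk2, ret, sep = ":")
  lab[is.na(exposure$retinopathy)] <- NA_character_
  if (scheme == "risk2_retinopathy") return(lab)
  slope <- exposure$slope_stratum
  lab2 <- paste(lab, slope, sep = ":")
  lab2[is.na(lab) | slope == "missing"] <- NA_character_
  lab2
}

#' @rdname assign_strata
#' @export
stratum_levels <- function(scheme = c("overall", "risk4",
                                      "risk2_retinopathy",
                                      "risk2_retinopathy_slope")) {
  scheme <- match.arg(scheme)
  risk2 <- c("low_moderate", "high_veryhigh")
  ret <- c("no_retinopathy", "retinopathy")
  slp <- c("ge0", "minus30to0", "lt_minus30")
  switch(scheme,
    overall = "all",
    risk4 = risk_category_levels(),
    risk2_retinopathy = as.vector(t(outer(risk2, ret, paste, sep = ":"))),
    risk2_retinopathy_slope = {
      g <- expand.grid(slope = slp, ret = ret, risk2 = risk2,
                       stringsAsFactors = FALSE)
      paste(g$risk2, g$ret, g$slope, sep = ":")
    }
  )
}
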