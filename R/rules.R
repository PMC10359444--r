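rule_directions <- function() c("absence_stable", "presence_worsening")

#' Count the contingency cells for one association rule
#'
#' Within one stratum, for a given factor, counts the subjects entering
#' the rule's four denominators. For the `presence_worsening` rule the
#' antecedent is presence of the factor and the consequent is worsening
#' kidney function; for `absence_stable` the antecedent is absence and
#' the consequent is stable kidney function. Subjects with a missing flag
#' for the factor are excluded from all four counts (per-factor
#' complete case).
#'
#' @param rows Exposure rows belonging to one stratum.
#' @param factor Factor name (must have a `risk_<factor>` column).
#' @param rule `"absence_stable"` or `"presence_worsening"`.
#' @return Named integer vector: `n_all`, `n_antecedent`, `n_joint`,
#'   `n_consequent`.
#' @examples
#' ex <- tibble::tibble(risk_x = c(TRUE, TRUE, FALSE, FALSE),
#'                      outcome = c("worsening", "stable", "stable", "stable"))
#' count_rule(ex, "x", "presence_worsening")
#' @export
count_rule <- function(rows, factor, rule = rule_directions()) {
  rule <- match.arg(rule)
  flag <- rows[[paste0("risk_", factor)]]
  if (is.null(flag)) stop("no flag column for factor `", factor, "`",
                          call. = FALSE)
  worsen <- rows$outcome == "worsening"
  keep <- !is.na(flag) & !is.na(worsen)
  flag <- flag[keep]; worsen <- worsen[keep]
  if (rule == "presence_worsening") {
    ant <- flag; cons <- worsen
  } else {
    ant <- !flag; cons <- !worsen
  }
  c(n_all = length(ant),
    n_antecedent = sum(ant),
    n_joint = sum(ant & cons),
    n_consequent = sum(cons))
}

#' Confidence, lift and significance from rule counts
#'
#' Confidence is `n_joint / n_antecedent` (undefined when the antecedent
#' is empty); lift is confidence divided by the consequent's base rate
#' `n_consequent / n_all` (undefined when either is undefined or the base
#' rate is zero). A rule is significant when lift is strictly greater
#' than 1; lift exactly 1 is not significant, and undefined values
#' propagate to `significant = FALSE`.
#'
#' @param counts Named vector or list with `n_all`, `n_antecedent`,
#'   `n_joint`, `n_consequent` (vectors are allowed and recycled
#'   position-wise).
#' @return A tibble with columns `confidence`, `lift`, `significant`.
#' @examples
#' score_rule(c(n_all = 10, n_antecedent = 4, n_joint = 2, n_consequent = 3))
#' @export
score_rule <- function(counts) {
  counts <- as.list(counts)
  n_all <- counts$n_all
  n_ant <- counts$n_antecedent
  n_joint <- counts$n_joint
  n_cons <- counts$n_consequent
  stopifnot(all(n_joint <= n_ant), all(n_ant <= n_all),
            all(n_cons <= n_all), all(n_joint >= 0))
  confidence <- ifelse(n_ant > 0, n_joint / n_ant, NA_real_)
  base <- ifelse(n_all > 0, n_cons / n_all, NA_real_)
  lift <- ifelse(!is.na(confidence) & !is.na(base) & base > 0,
                 confidence / base, NA_real_)
  tibble::tibble(confidence = confidence, lift = lift,
                 significant = !is.na(lift) & lift > 1)
}

# Vectorised counting across all rule factors for one stratum subset.
count_stratum <- function(flag_mat, worsen, idx) {
  f <- flag_mat[idx, , drop = FALSE]
  w <- worsen[idx]
  miss <- is.na(f)
  cs <- function(x) unname(colSums(x, na.rm = TRUE))
  pres <- f & !miss
  abs_ <- (!f) & !miss
  list(
    presence_worsening = tibble::tibble(
      n_all = cs(!miss),
      n_antecedent = cs(pres),
      n_joint = cs(pres & w),
      n_consequent = cs((!miss) & w)
    ),
    absence_stable = tibble::tibble(
      n_all = cs(!miss),
      n_antecedent = cs(abs_),
      n_joint = cs(abs_ & !w),
      n_consequent = cs((!miss) & !w)
    )
  )
}

#' Mine all association rules across strata and schemes
#'
#' Produces one result row per (scheme, stratum, factor, rule direction):
#' the complete cross-product over the scheme's canonical strata and the
#' rule factors in `specs`, with empty or undefined cells retained
#' (`confidence`/`lift` are `NA` there). Deterministic, with bit-stable
#' row ordering by scheme, stratum, factor and rule.
#'
#' @param exposure A `dkd_exposure` table from [build_exposure_table()].
#' @param schemes Character vector of scheme names (see
#'   [assign_strata()]).
#' @param specs Factor specifications; defaults to those attached to
#'   `exposure`.
#' @return A tibble of class `dkd_rules` with columns `scheme`,
#'   `stratum`, `factor`, `rule`, the four counts, `confidence`, `lift`,
#'   `significant`.
#' @examples
#' v <- simulate_cohort(cohort_profile(n_subjects = 400, seed = 4))
#' rules <- mine_rules(build_exposure_table(assemble_cohort(v)))
#' dplyr::filter(rules, significant, rule == "presence_worsening")
#' @export
mine_rules <- function(exposure,
                       schemes = c("overall", "risk4", "risk2_retinopathy",
                                   "risk2_retinopathy_slope"),
                       specs = attr(exposure, "specs")) {
  if (is.null(specs)) specs <- risk_factor_specs()
  fx <- rule_factors(specs)
  cols <- paste0("risk_", fx)
  miss_cols <- setdiff(cols, names(exposure))
  if (length(miss_cols)) {
    stop("exposure table lacks flag column(s): ",
         paste(miss_cols, collapse = ", "), call. = FALSE)
  }
  flag_mat <- as.matrix(as.data.frame(exposure[, cols]))
  colnames(flag_mat) <- fx
  worsen <- exposure$outcome == "worsening"

  res <- purrr::map(schemes, function(sc) {
    labs <- assign_strata(exposure, sc)
    purrr::map(stratum_levels(sc), function(lv) {
      cnt <- count_stratum(flag_mat, worsen, which(!is.na(labs) & labs == lv))
      purrr::imap(cnt[rule_directions()], function(tb, dir) {
        dplyr::bind_cols(
          tibble::tibble(scheme = sc, stratum = lv, factor = fx, rule = dir),
          tb
        )
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  res <- dplyr::bind_cols(res, score_rule(res[, c("n_all", "n_antecedent",
                                                  "n_joint",
                                                  "n_consequent")]))
  lev_key <- unlist(lapply(schemes,
                           function(sc) paste(sc, stratum_levels(sc))))
  res <- res |>
    dplyr::arrange(match(.data$scheme, schemes),
                   match(paste(.data$scheme, .data$stratum), lev_key),
                   match(.data$factor, fx), .data$rule)
  structure(res, specs = specs, schemes = schemes,
            class = c("dkd_rules", class(tibble::tibble())))
}

#' @export
print.dkd_rules <- function(x, ...) {
  if ("scheme" %in% names(x)) {
    cat("<dkd_rules> ", nrow(x), " cells across schemes: ",
        paste(unique(x$scheme), collapse = ", "), "\n", sep = "")
  }
  NextMethod()
}

#' Rule results as a plain tibble
#' @param x A `dkd_rules` object.
#' @param ... Unused.
#' @export
tidy.dkd_rules <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a mined rule set
#' @param x A `dkd_rules` object.
#' @param ... Unused.
#' @export
glance.dkd_rules <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_defined = sum(!is.na(x$confidence)),
    n_significant = sum(x$significant),
    n_schemes = length(unique(x$scheme)),
    n_factors = length(unique(x$factor))
  )
}
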