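#' Marginal lab distributions for the two default cohorts
#'
#' Per-analyte mean and standard deviation used by [simulate_cohort()] when
#' drawing baseline values. The defaults describe, respectively, a general
#' community diabetic population (older, balanced sex ratio) and a
#' working-age employee diabetic population (younger, predominantly male,
#' higher liver enzymes and BMI). Each element is a length-2 numeric
#' `c(mean, sd)`; units follow the cohort CSV schema (eGFR in
#' mL/min/1.73m^2, glucose in mmol/L, lipids in mg/dL, pressures in mmHg).
#'
#' @return Named list of length-2 numeric vectors, one per analyte.
#' @seealso [cohort_profile()]
#' @export
general_marginals <- function() {
  list(
    egfr            = c(75.0, 18.3),
    hba1c           = c(7.4, 1.3),
    fasting_glucose = c(7.7, 2.4),
    hemoglobin      = c(13.9, 1.5),
    ast             = c(28.1, 15.7),
    alt             = c(28.9, 22.6),
    ggt             = c(50.2, 67.4),
    total_chol      = c(208.2, 37.4),
    triglyceride    = c(150.6, 93.1),
    hdl             = c(57.8, 15.8),
    ldl             = c(120.3, 34.1),
    sbp             = c(135.1, 17.7),
    dbp             = c(78.3, 10.8),
    bmi             = c(24.1, 3.4)
  )
}

#' @rdname general_marginals
#' @export
worker_marginals <- function() {
  list(
    egfr            = c(80.1, 16.1),
    hba1c           = c(7.3, 1.4),
    fasting_glucose = c(8.2, 2.4),
    hemoglobin      = c(15.3, 1.3),
    ast             = c(30.5, 18.9),
    alt             = c(41.7, 32.1),
    ggt             = c(72.7, 75.1),
    total_chol      = c(214.7, 39.5),
    triglyceride    = c(179.4, 144.1),
    hdl             = c(53.4, 13.1),
    ldl             = c(130.6, 32.4),
    sbp             = c(130.2, 16.9),
    dbp             = c(83.5, 11.9),
    bmi             = c(26.7, 4.0)
  )
}

#' Default relative risks linking risk-factor presence to kidney worsening
#'
#' The per-factor relative risk of the worsening trajectory given latent
#' presence of the factor, multiplied together across present factors and
#' applied to `worsening_base_rate`. Glycemic factors and proteinuria carry
#' the largest effects, anemia, reduced eGFR, blood pressure, obesity and
#' lipids moderate ones; all remaining factors are null (RR 1). These are
#' simulation conventions, not estimates from any cohort.
#'
#' @return Named numeric vector of relative risks (> 0).
#' @export
default_effect_map <- function() {
  c(
    hba1c = 2.5, fasting_glucose = 2.2, urine_protein = 2.4,
    hemoglobin = 1.8, egfr = 1.6, sbp = 1.5, bmi = 1.4,
    triglyceride = 1.3, hdl = 1.3
  )
}

#' Describe a synthetic diabetic cohort
#'
#' Builds the parameter object consumed by [simulate_cohort()]. All
#' fractions are in `[0, 1]`; `marginal_params` is a named list of
#' `c(mean, sd)` per analyte (see [general_marginals()]); `effect_map` is a
#' named vector of relative risks of the worsening outcome given latent
#' presence of each factor. The per-subject worsening probability is
#' `worsening_base_rate * prod(effect_map[present factors])`, capped at 1.
#'
#' @param cohort_kind `"general"` or `"worker"`. Worker cohorts carry
#'   ESKD/dialysis/transplant event flags that also count as worsening.
#' @param n_subjects Number of subjects to simulate.
#' @param baseline_year First examination year.
#' @param followup_years Annual follow-up visits after baseline (default 5,
#'   the outcome window).
#' @param age_mean,age_sd,age_min Baseline age distribution (years),
#'   truncated below at `age_min`.
#' @param prop_female Fraction of female subjects.
#' @param marginal_params Named list of `c(mean, sd)` per analyte.
#' @param prop_proteinuria Fraction with dipstick proteinuria >= 1+.
#' @param prop_trace Among non-proteinuric subjects, fraction graded
#'   "trace" rather than "negative".
#' @param prop_2plus Among proteinuric subjects, fraction graded "2+"
#'   (the remainder are "1+"); default 0 so only the binary split the
#'   analysis uses is exercised.
#' @param prop_retinopathy Fraction with diabetic retinopathy.
#' @param prop_retinopathy_missing Fraction with retinopathy status missing
#'   at random (default 0).
#' @param prop_dm_treatment Fraction on diabetes treatment.
#' @param worsening_base_rate Worsening probability with no risk factors
#'   present.
#' @param effect_map Named numeric vector of relative risks (> 0); factors
#'   absent from the map have RR 1.
#' @param eskd_rate Worker cohorts only: per-subject probability of an
#'   ESKD-type event during follow-up (default 0).
#' @param latent_flag_rate Marginal probability of latent presence of each
#'   continuous risk factor (default 0.2, matching the 20% tail cut used
#'   for binarization).
#' @param seed Integer seed; simulation is deterministic given the profile.
#' @return A list with class `"cohort_profile"`.
#' @examples
#' p <- cohort_profile(n_subjects = 100, seed = 1)
#' head(simulate_cohort(p))
#' @export
cohort_profile <- function(cohort_kind = c("general", "worker"),
                           n_subjects = 2000,
                           baseline_year = 2005L,
                           followup_years = 5L,
                           age_mean = 66.7, age_sd = 7.7, age_min = 40,
                           prop_female = 0.469,
                           marginal_params = general_marginals(),
                           prop_proteinuria = 0.116,
                           prop_trace = 0.5,
                           prop_2plus = 0,
                           prop_retinopathy = 0.20,
                           prop_retinopathy_missing = 0,
                           prop_dm_treatment = 0.5,
                           worsening_base_rate = 0.05,
                           effect_map = NULL,
                           eskd_rate = 0,
                           latent_flag_rate = 0.2,
                           seed = 1L) {
  cohort_kind <- match.arg(cohort_kind)
  if (is.null(effect_map)) effect_map <- c(hba1c = 1)[0]
  profile <- structure(
    list(
      cohort_kind = cohort_kind,
      n_subjects = as.integer(n_subjects),
      baseline_year = as.integer(baseline_year),
      followup_years = as.integer(followup_years),
      age_mean = age_mean, age_sd = age_sd, age_min = age_min,
      prop_female = prop_female,
      marginal_params = marginal_params,
      prop_proteinuria = prop_proteinuria,
      prop_trace = prop_trace,
      prop_2plus = prop_2plus,
      prop_retinopathy = prop_retinopathy,
      prop_retinopathy_missing = prop_retinopathy_missing,
      prop_dm_treatment = prop_dm_treatment,
      worsening_base_rate = worsening_base_rate,
      effect_map = effect_map,
      eskd_rate = eskd_rate,
      latent_flag_rate = latent_flag_rate,
      seed = as.integer(seed)
    ),
    class = "cohort_profile"
  )
  validate_profile(profile)
}

validate_profile <- function(profile) {
  stopifnot(inherits(profile, "cohort_profile"))
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop("invalid profile: `", nm, "` must be a fraction in [0, 1]",
           call. = FALSE)
    }
  }
  for (nm in c("prop_female", "prop_proteinuria", "prop_trace", "prop_2plus",
               "prop_retinopathy", "prop_retinopathy_missing",
               "prop_dm_treatment", "worsening_base_rate", "eskd_rate",
               "latent_flag_rate")) {
    chk_frac(profile[[nm]], nm)
  }
  if (profile$n_subjects < 1L) {
    stop("invalid profile: `n_subjects` must be >= 1", call. = FALSE)
  }
  if (profile$followup_years < 1L) {
    stop("invalid profile: `followup_years` must be >= 1", call. = FALSE)
  }
  if (profile$age_sd <= 0 || profile$age_mean <= 0) {
    stop("invalid profile: `age_mean` and `age_sd` must be positive",
         call. = FALSE)
  }
  if (length(profile$effect_map) &&
      (is.null(names(profile$effect_map)) ||
       any(!nzchar(names(profile$effect_map))))) {
    stop("invalid profile: `effect_map` must be a named vector",
         call. = FALSE)
  }
  if (any(profile$effect_map <= 0)) {
    stop("invalid profile: `effect_map` values must be > 0", call. = FALSE)
  }
  bad <- vapply(profile$marginal_params,
                function(p) length(p) != 2L || any(!is.finite(p)) || p[2] <= 0,
                logical(1))
  if (any(bad)) {
    stop("invalid profile: `marginal_params` entries must be c(mean, sd > 0): ",
         paste(names(which(bad)), collapse = ", "), call. = FALSE)
  }
  profile
}

#' Ready-made profiles for the two default cohorts
#'
#' `general_profile()` describes an older community diabetic cohort
#' (n = 4935, mean age 66.7, 46.9% female, 11.6% proteinuric);
#' `worker_profile()` a working-age employee diabetic cohort (n = 2153,
#' mean age 47.8, 3.8% female, 29.1% proteinuric). Both use
#' [default_effect_map()] and calibrate `worsening_base_rate` so the
#' expected five-year worsening fraction equals `target_worsening`
#' (defaults 4.8% and 5.1%).
#'
#' @param n_subjects,seed Passed to [cohort_profile()].
#' @param target_worsening Expected marginal worsening fraction to
#'   calibrate the base rate to.
#' @param ... Further overrides passed to [cohort_profile()].
#' @return A `cohort_profile`.
#' @export
general_profile <- function(n_subjects = 4935, seed = 1L,
                            target_worsening = 0.048, ...) {
  p <- cohort_profile(
    cohort_kind = "general", n_subjects = n_subjects,
    age_mean = 66.7, age_sd = 7.7, age_min = 40,
    prop_female = 0.469, marginal_params = general_marginals(),
    prop_proteinuria = 0.116, prop_retinopathy = 0.20,
    prop_dm_treatment = 0.5,
    effect_map = default_effect_map(), seed = seed, ...
  )
  calibrate_worsening_rate(p, target_worsening)
}

#' @rdname general_profile
#' @export
worker_profile <- function(n_subjects = 2153, seed = 1L,
                           target_worsening = 0.051, ...) {
  p <- cohort_profile(
    cohort_kind = "worker", n_subjects = n_subjects,
    age_mean = 47.8, age_sd = 5.5, age_min = 20,
    prop_female = 0.038, marginal_params = worker_marginals(),
    prop_proteinuria = 0.291, prop_retinopathy = 0.15,
    prop_dm_treatment = 0.4,
    effect_map = default_effect_map(), seed = seed, ...
  )
  calibrate_worsening_rate(p, target_worsening)
}

# Marginal latent-presence probability for each factor named in the effect
# map. Continuous factors share latent_flag_rate; proteinuria uses its own
# prevalence; retinopathy its own.
effect_factor_probs <- function(profile) {
  fx <- names(profile$effect_map)
  p <- rep(profile$latent_flag_rate, length(fx))
  names(p) <- fx
  if ("urine_protein" %in% fx) p[["urine_protein"]] <- profile$prop_proteinuria
  if ("retinopathy" %in% fx) p[["retinopathy"]] <- profile$prop_retinopathy
  p
}

#' Expected worsening fraction and designed conditional probabilities
#'
#' `expected_worsening_rate()` computes the exact marginal probability of
#' the worsening trajectory implied by a profile, by enumerating all
#' presence/absence combinations of the factors carrying a non-unit
#' relative risk (latent states are independent; the per-state probability
#' is `base * prod(RR)` capped at 1). `designed_worsening_probability()`
#' conditions on the latent state of one factor, giving the generator's
#' ground-truth `P(worsen | factor present)` against which empirical
#' confidences can be checked.
#'
#' @param profile A `cohort_profile`.
#' @param factor Factor name to condition on (must appear in the effect map
#'   or be a continuous factor, in which case its latent rate is used).
#' @param present Condition on presence (`TRUE`) or absence.
#' @return A single probability.
#' @export
expected_worsening_rate <- function(profile) {
  enumerate_worsening(profile, condition = NULL)
}

#' @rdname expected_worsening_rate
#' @export
designed_worsening_probability <- function(profile, factor, present = TRUE) {
  enumerate_worsening(profile, condition = stats::setNames(present, factor))
}

enumerate_worsening <- function(profile, condition = NULL) {
  base <- profile$worsening_base_rate
  rr <- profile$effect_map
  rr <- rr[rr != 1]
  pr <- effect_factor_probs(profile)[names(rr)]
  if (!is.null(condition)) {
    f <- names(condition)
    if (!f %in% names(rr)) {
      # Null factor: independent of the outcome mechanism.
      rr <- c(rr, stats::setNames(1, f))
      pr <- c(pr, stats::setNames(profile$latent_flag_rate, f))
    }
    pr[f] <- as.numeric(condition)
  }
  k <- length(rr)
  if (k == 0L) return(min(1, base))
  states <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
  w_state <- apply(states, 1, function(s) prod(ifelse(s == 1, pr, 1 - pr)))
  p_state <- pmin(1, base * apply(states, 1, function(s) prod(rr^s)))
  sum(w_state * p_state)
}

#' @rdname expected_worsening_rate
#' @param target Marginal worsening fraction the base rate should imply.
#' @details `calibrate_worsening_rate()` solves for the base rate whose
#'   expected marginal worsening fraction equals `target`, accounting for
#'   the cap at probability 1, and returns the updated profile.
#' @export
calibrate_worsening_rate <- function(profile, target) {
  stopifnot(target >= 0, target <= 1)
  if (target == 0) {
    profile$worsening_base_rate <- 0
    return(profile)
  }
  f <- function(b) {
    q <- profile
    q$worsening_base_rate <- b
    expected_worsening_rate(q) - target
  }
  profile$worsening_base_rate <-
    stats::uniroot(f, c(0, 1), tol = 1e-12)$root
  profile
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat("<cohort_profile> ", x$cohort_kind, ", n = ", x$n_subjects,
      ", baseline ", x$baseline_year, ", follow-up ", x$followup_years,
      " y\n", sep = "")
  cat("  base worsening rate ", signif(x$worsening_base_rate, 4),
      "; expected marginal rate ",
      signif(expected_worsening_rate(x), 4), "\n", sep = "")
  if (length(x$effect_map)) {
    cat("  effects:", paste(names(x$effect_map), signif(x$effect_map, 3),
                            sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
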