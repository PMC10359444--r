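# Quantile function of a normal truncated to (0, Inf); used for age.
qnorm_pos <- function(u, mean, sd) {
  a <- stats::pnorm(0, mean, sd)
  stats::qnorm(a + u * (1 - a), mean, sd)
}

# Quantile function of the lognormal with the given arithmetic mean and
# SD (moment matching). Lab values are positive and right-skewed; the
# lognormal reproduces the requested mean/SD exactly, which a
# zero-truncated normal cannot for high-CV analytes such as GGT.
qlnorm_ms <- function(u, mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  stats::qlnorm(u, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Draw n values from the lognormal marginal, placing subjects with latent
# risk in the direction-appropriate tail of size `tail` (in quantile
# space) and the rest in the body. The mixture marginal is exactly the
# lognormal when P(latent) == tail.
draw_factor_values <- function(latent, mean, sd, direction, tail) {
  n <- length(latent)
  u <- stats::runif(n)
  q <- if (direction == "high_is_risk") {
    ifelse(latent, (1 - tail) + u * tail, u * (1 - tail))
  } else {
    ifelse(latent, u * tail, tail + u * (1 - tail))
  }
  qlnorm_ms(q, mean, sd)
}

# Invert the Japanese eGFR equation: creatinine giving this eGFR at this
# age/sex.
creatinine_for_egfr <- function(egfr, age, sex) {
  k <- 194 * age^(-0.287) * ifelse(sex == "female", 0.739, 1)
  (egfr / k)^(-1 / 1.094)
}

#' Simulate a longitudinal diabetic health-examination cohort
#'
#' Generates one row per subject-visit with the schema described in
#' [cohort_schema()]: annual examinations from `baseline_year` through
#' `baseline_year + followup_years`, lab values drawn from lognormal
#' marginals moment-matched to each analyte's mean and SD, dipstick
#' proteinuria, retinopathy and treatment flags, and a
#' serum-creatinine trajectory per subject.
#'
#' Each subject carries latent binary risk states: one per continuous
#' analyte (marginal probability `latent_flag_rate`, realised by sampling
#' the analyte from the risk tail or the body of its marginal so that
#' percentile binarization downstream re-identifies the state), plus
#' dipstick proteinuria and retinopathy with their own prevalences. The
#' probability of the worsening trajectory is
#' `worsening_base_rate * prod(effect_map[present factors])`, capped at 1.
#' Worsening subjects follow a linear eGFR decline crossing -30% from
#' baseline at a uniformly random time in `[1, followup_years]` and
#' continuing at that slope; stable subjects keep their baseline creatinine
#' up to i.i.d. +-3% measurement noise (their eGFR still drifts down
#' slowly with age). Other analytes are re-measured at follow-ups with
#' +-2% noise.
#'
#' Deterministic given the profile (including its `seed`). The ground
#' truth is attached as `attr(, "latent")`: a tibble with one row per
#' subject holding every latent risk state, the designed per-subject
#' worsening probability and the realised worsening indicator.
#'
#' @param profile A [cohort_profile()].
#' @return A tibble of visit records, ordered by subject and year, with
#'   the latent-truth tibble attached as attribute `"latent"`.
#' @examples
#' v <- simulate_cohort(cohort_profile(n_subjects = 50, seed = 7))
#' dplyr::count(v, year)
#' @export
simulate_cohort <- function(profile) {
  validate_profile(profile)
  withr::with_seed(profile$seed, simulate_cohort_impl(profile))
}

simulate_cohort_impl <- function(profile) {
  n <- profile$n_subjects
  fu <- profile$followup_years
  analytes <- names(profile$marginal_params)
  tail <- profile$latent_flag_rate

  subject_id <- sprintf("S%06d", seq_len(n))
  sex <- ifelse(stats::runif(n) < profile$prop_female, "female", "male")
  age0 <- pmax(profile$age_min,
               round(qnorm_pos(stats::runif(n) *
                                 (1 - stats::pnorm(profile$age_min,
                                                   profile$age_mean,
                                                   profile$age_sd)) +
                                 stats::pnorm(profile$age_min,
                                              profile$age_mean,
                                              profile$age_sd),
                               profile$age_mean, profile$age_sd)))

  # Latent risk states and baseline analyte values.
  latent <- tibble::tibble(subject_id = subject_id)
  values0 <- list()
  for (a in analytes) {
    st <- stats::runif(n) < tail
    latent[[paste0("risk_", a)]] <- st
    dir <- if (a %in% c("egfr", "hemoglobin", "hdl")) "low_is_risk" else "high_is_risk"
    mp <- profile$marginal_params[[a]]
    values0[[a]] <- draw_factor_values(st, mp[1], mp[2], dir, tail)
  }

  proteinuric <- stats::runif(n) < profile$prop_proteinuria
  latent$risk_urine_protein <- proteinuric
  dip_pos <- ifelse(stats::runif(n) < profile$prop_2plus, "2+", "1+")
  dip_neg <- ifelse(stats::runif(n) < profile$prop_trace, "trace", "negative")
  dipstick <- ifelse(proteinuric, dip_pos, dip_neg)

  retinopathy <- stats::runif(n) < profile$prop_retinopathy
  latent$risk_retinopathy <- retinopathy
  retinopathy[stats::runif(n) < profile$prop_retinopathy_missing] <- NA

  on_tx <- stats::runif(n) < profile$prop_dm_treatment

  # Designed worsening probability per subject from the latent states.
  p_worsen <- rep(profile$worsening_base_rate, n)
  for (f in names(profile$effect_map)) {
    st <- latent[[paste0("risk_", f)]]
    if (is.null(st)) next
    p_worsen <- p_worsen * ifelse(st, profile$effect_map[[f]], 1)
  }
  p_worsen <- pmin(1, p_worsen)
  worsen <- stats::runif(n) < p_worsen
  t_cross <- stats::runif(n, 1, fu) # eGFR crosses -30% here if worsening

  eskd <- profile$cohort_kind == "worker" &
    stats::runif(n) < profile$eskd_rate
  eskd_year <- sample.int(fu, n, replace = TRUE)

  latent$p_worsen <- p_worsen
  latent$worsen <- worsen

  egfr0 <- values0$egfr
  cr0 <- creatinine_for_egfr(egfr0, age0, sex)

  # Expand to visits: years 0..fu relative to baseline.
  nv <- fu + 1L
  idx <- rep(seq_len(n), each = nv)
  t_rel <- rep(0:fu, times = n)
  age_v <- age0[idx] + t_rel
  sex_v <- sex[idx]

  # Creatinine trajectory.
  ratio <- 1 - 0.3 * t_rel / t_cross[idx]          # worsening path
  ratio <- pmax(ratio, 0.05)
  egfr_w <- egfr0[idx] * ratio
  cr_w <- creatinine_for_egfr(egfr_w, age_v, sex_v)
  cr_s <- cr0[idx] * stats::runif(n * nv, 0.97, 1.03) # stable path
  cr_s[t_rel == 0L] <- cr0[idx][t_rel == 0L]
  creat <- round(ifelse(worsen[idx], cr_w, cr_s), 4)

  visits <- tibble::tibble(
    subject_id = subject_id[idx],
    year = profile$baseline_year + t_rel,
    age = age_v,
    sex = sex_v,
    serum_creatinine = creat,
    dipstick_protein = dipstick[idx]
  )
  noise <- function(x) round(x[idx] * ifelse(t_rel == 0L, 1,
                                             stats::runif(n * nv, 0.98, 1.02)), 2)
  for (a in setdiff(analytes, "egfr")) visits[[a]] <- noise(values0[[a]])
  visits$retinopathy <- retinopathy[idx]
  visits$on_dm_treatment <- on_tx[idx]
  visits$eskd_event <- eskd[idx] & t_rel == eskd_year[idx]

  visits <- visits[, cohort_schema()$column]
  attr(visits, "latent") <- latent
  visits
}
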