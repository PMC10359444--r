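# Build a visit-record tibble from per-visit vectors, filling the full
# cohort schema with benign defaults.
make_visits <- function(subject_id, year,
                        serum_creatinine = 1.0,
                        age = 60, sex = "male",
                        dipstick_protein = "negative",
                        hba1c = 7.5, fasting_glucose = 8.0,
                        hemoglobin = 14, ast = 25, alt = 25, ggt = 40,
                        total_chol = 200, triglyceride = 140, hdl = 55,
                        ldl = 120, sbp = 130, dbp = 80, bmi = 24,
                        retinopathy = FALSE, on_dm_treatment = FALSE,
                        eskd_event = FALSE) {
  n <- max(length(subject_id), length(year))
  tibble::tibble(
    subject_id = rep_len(subject_id, n), year = as.integer(rep_len(year, n)),
    age = rep_len(age, n), sex = rep_len(sex, n),
    serum_creatinine = rep_len(serum_creatinine, n),
    dipstick_protein = rep_len(dipstick_protein, n),
    hba1c = rep_len(hba1c, n), fasting_glucose = rep_len(fasting_glucose, n),
    hemoglobin = rep_len(hemoglobin, n), ast = rep_len(ast, n),
    alt = rep_len(alt, n), ggt = rep_len(ggt, n),
    total_chol = rep_len(total_chol, n),
    triglyceride = rep_len(triglyceride, n), hdl = rep_len(hdl, n),
    ldl = rep_len(ldl, n), sbp = rep_len(sbp, n), dbp = rep_len(dbp, n),
    bmi = rep_len(bmi, n), retinopathy = rep_len(retinopathy, n),
    on_dm_treatment = rep_len(on_dm_treatment, n),
    eskd_event = rep_len(eskd_event, n)
  )
}

# A subject whose creatinine trajectory realises the given eGFR percent
# changes at annual follow-ups (baseline year 2000, fixed age/sex so the
# mapping is exact by inverting the eGFR equation).
visits_with_egfr_path <- function(subject_id, baseline_egfr, pct_changes,
                                  sex = "male", age0 = 60) {
  egfr <- c(baseline_egfr, baseline_egfr * (1 + pct_changes / 100))
  years <- 2000L + seq_along(egfr) - 1L
  ages <- age0 + seq_along(egfr) - 1L
  k <- 194 * ages^(-0.287) * ifelse(sex == "female", 0.739, 1)
  make_visits(subject_id, years, serum_creatinine = (egfr / k)^(-1 / 1.094),
              age = ages, sex = sex)
}

# Independent brute-force oracle for rule counting/scoring: an explicit
# loop over rows, written against the four formula denominators, sharing
# no code with the package implementation.
oracle_rule <- function(rows, factor, rule) {
  n_all <- 0L; n_ant <- 0L; n_joint <- 0L; n_cons <- 0L
  for (i in seq_len(nrow(rows))) {
    flag <- rows[[paste0("risk_", factor)]][i]
    out <- rows$outcome[i]
    if (is.na(flag) || is.na(out)) next
    n_all <- n_all + 1L
    ant <- if (rule == "presence_worsening") flag else !flag
    cons <- if (rule == "presence_worsening") out == "worsening"
            else out == "stable"
    if (ant) n_ant <- n_ant + 1L
    if (ant && cons) n_joint <- n_joint + 1L
    if (cons) n_cons <- n_cons + 1L
  }
  conf <- if (n_ant > 0) n_joint / n_ant else NA_real_
  lift <- if (!is.na(conf) && n_cons > 0) conf / (n_cons / n_all) else NA_real_
  list(n_all = n_all, n_antecedent = n_ant, n_joint = n_joint,
       n_consequent = n_cons, confidence = conf, lift = lift,
       significant = !is.na(lift) && lift > 1)
}

# Random small exposure-outcome table with missing flags.
random_exposure <- function(n, factors = c("a", "b"), p_missing = 0.1) {
  out <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    outcome = sample(c("stable", "worsening"), n, replace = TRUE,
                     prob = c(0.7, 0.3))
  )
  for (f in factors) {
    fl <- sample(c(TRUE, FALSE), n, replace = TRUE)
    fl[stats::runif(n) < p_missing] <- NA
    out[[paste0("risk_", f)]] <- fl
  }
  out
}
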