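test_that("default factor specifications encode the field's risk directions", {
  specs <- risk_factor_specs()
  expect_identical(nrow(specs), 17L)
  spec_of <- function(f) specs[specs$factor == f, ]
  expect_identical(spec_of("hemoglobin")$direction, "low_is_risk")
  expect_identical(spec_of("hdl")$direction, "low_is_risk")
  expect_identical(spec_of("egfr")$direction, "low_is_risk")
  expect_identical(spec_of("sbp")$direction, "high_is_risk")
  expect_identical(spec_of("urine_protein")$categorical_rule,
                   "dipstick >= 1+")
  # retinopathy and the 2-year slope stratify but do not enter rules
  expect_identical(spec_of("retinopathy")$role, "stratifier")
  expect_identical(spec_of("egfr_2y_change")$role, "stratifier")
  expect_identical(sum(specs$role == "rule"), 15L)
  expect_identical(
    sum(risk_factor_specs(include_retinopathy = TRUE)$role == "rule"), 16L)
  expect_error(risk_factor_specs(percentile = 15), "10 or 20")
})

test_that("thresholds flag the intended tail fraction per sex", {
  base <- tibble::tibble(
    subject_id = sprintf("S%03d", 1:100),
    sex = "male",
    sbp = as.numeric(1:100)
  )
  specs <- risk_factor_specs()[risk_factor_specs()$factor == "sbp", ]
  thr20 <- compute_thresholds(base, specs, percentile = 20)
  expect_equal(thr20$threshold, stats::quantile(1:100, 0.8, names = FALSE))
  expect_identical(sum(base$sbp > thr20$threshold), 20L)

  thr10 <- compute_thresholds(base, specs, percentile = 10)
  expect_identical(sum(base$sbp > thr10$threshold), 10L)

  # low_is_risk uses the lower tail
  specs_hgb <- risk_factor_specs()[risk_factor_specs()$factor == "hemoglobin", ]
  base$hemoglobin <- as.numeric(1:100)
  thr_h <- compute_thresholds(base, specs_hgb, percentile = 20)
  expect_equal(thr_h$threshold, stats::quantile(1:100, 0.2, names = FALSE))
  expect_identical(sum(base$hemoglobin < thr_h$threshold), 20L)

  # constant factor: threshold equals the constant, nobody exceeds strictly
  base$sbp <- 120
  thr_c <- compute_thresholds(base, specs, percentile = 20)
  expect_identical(sum(base$sbp > thr_c$threshold), 0L)

  # all-missing (factor, sex) pair errors with the pair named
  base$sbp <- NA_real_
  expect_error(compute_thresholds(base, specs), "sbp.*male")
})

test_that("binarization is strict at the boundary and per-factor for missingness", {
  base <- make_visits(sprintf("S%02d", 1:10), 2000)
  base$sbp <- as.numeric(101:110)
  base$hdl <- as.numeric(41:50)
  base$hdl[3] <- NA
  base$dipstick_protein <- c("negative", "trace", "1+", "2+",
                             rep("negative", 6))
  base$egfr <- egfr_japanese(base$serum_creatinine, base$age, base$sex)
  specs <- risk_factor_specs()
  thr <- compute_thresholds(base, specs)
  flags <- binarize_risk_factors(base, thr, specs)

  sbp_thr <- thr$threshold[thr$factor == "sbp"]
  # a value exactly at the threshold is absent
  base2 <- base; base2$sbp[1] <- sbp_thr
  flags2 <- binarize_risk_factors(base2, thr, specs)
  expect_false(flags2$risk_sbp[1])
  expect_identical(flags$risk_sbp, base$sbp > sbp_thr)

  # dipstick: negative/trace absent, >= 1+ present
  expect_identical(flags$risk_urine_protein[1:4],
                   c(FALSE, FALSE, TRUE, TRUE))

  # missing HDL gives a missing flag for HDL only
  expect_true(is.na(flags$risk_hdl[3]))
  expect_false(anyNA(flags$risk_sbp))
})

test_that("tie-free flagged fractions stay within 2/n of the nominal tail", {
  withr::with_seed(4281, {
    n <- 500
    base <- make_visits(sprintf("S%04d", 1:n), 2000,
                        sex = rep(c("male", "female"), length.out = n))
    base$sbp <- stats::rnorm(n, 130, 15)
    base$egfr <- stats::rnorm(n, 75, 15)
  })
  specs <- risk_factor_specs()[risk_factor_specs()$factor %in%
                                 c("sbp", "egfr"), ]
  for (pct in c(20, 10)) {
    thr <- compute_thresholds(base, specs, percentile = pct)
    flags <- binarize_risk_factors(base, thr, specs)
    for (sx in c("male", "female")) {
      nsx <- sum(base$sex == sx)
      for (f in c("sbp", "egfr")) {
        frac <- mean(flags[[paste0("risk_", f)]][base$sex == sx])
        expect_lt(abs(frac - pct / 100), 2 / nsx + 1e-12)
      }
    }
  }
})

test_that("binarization is invariant under strictly monotone transforms", {
  withr::with_seed(4282, {
    base <- make_visits(sprintf("S%03d", 1:150), 2000)
    base$ggt <- stats::rlnorm(150, 3.5, 0.8)
  })
  specs <- risk_factor_specs()[risk_factor_specs()$factor == "ggt", ]
  f1 <- binarize_risk_factors(base, compute_thresholds(base, specs), specs)
  base_t <- base; base_t$ggt <- log(base$ggt)
  f2 <- binarize_risk_factors(base_t, compute_thresholds(base_t, specs),
                              specs)
  expect_identical(f1$risk_ggt, f2$risk_ggt)
})

test_that("flags recover the generator's latent risk states", {
  p <- cohort_profile(n_subjects = 2500, seed = 429)
  v <- simulate_cohort(p)
  ex <- build_exposure_table(assemble_cohort(v))
  lat <- attr(v, "latent")
  lat <- lat[match(ex$subject_id, lat$subject_id), ]
  for (f in c("hba1c", "hemoglobin", "ggt", "egfr", "urine_protein")) {
    acc <- mean(ex[[paste0("risk_", f)]] == lat[[paste0("risk_", f)]])
    expect_gt(acc, 0.9)
  }
})
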