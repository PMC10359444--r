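test_that("diabetes definition follows the three criteria with missing fields not met", {
  expect_true(is_diabetic(6.5, 5.0, FALSE))
  expect_false(is_diabetic(6.4, 6.9, FALSE))
  expect_true(is_diabetic(NA, NA, TRUE))
  expect_true(is_diabetic(5.0, 7.0, FALSE))
  expect_false(is_diabetic(5.0, NA, NA))
  expect_error(is_diabetic(NA, NA, NA), "indeterminate")
})

test_that("baseline is the earliest creatinine visit with enough follow-up span", {
  v <- make_visits("A", 2000:2006)
  expect_identical(select_baseline(v)$baseline_year, 2000L)

  # first visit lacks creatinine, so baseline moves to the next year
  v2 <- make_visits("B", 2000:2006)
  v2$serum_creatinine[1] <- NA
  expect_identical(select_baseline(v2)$baseline_year, 2001L)

  # span 3 < 5: no qualifying baseline
  v3 <- make_visits("C", c(2000L, 2003L))
  expect_true(is.na(select_baseline(v3)$baseline_year))

  # 6 years but only the later visits could anchor a 5-year span
  v4 <- make_visits("D", c(2000L, 2001L, 2006L))
  expect_identical(select_baseline(v4)$baseline_year, 2000L)
})

test_that("eligibility cascade retains the right subjects and attributes reasons", {
  ok <- make_visits("ok", 2000:2005)
  nondm <- make_visits("nondm", 2000:2005, hba1c = 6.0,
                       fasting_glucose = 6.0)
  short <- make_visits("short", 2000:2002)
  v <- dplyr::bind_rows(ok, nondm, short)

  coh <- assemble_cohort(v)
  expect_identical(glance(coh)$n_final, 1L)
  expect_identical(sort(unique(coh$visits$subject_id)), "ok")
  reasons <- tidy(coh)
  expect_identical(reasons$reason[reasons$subject_id == "nondm"],
                   "not_diabetic")
  expect_identical(reasons$reason[reasons$subject_id == "short"],
                   "insufficient_followup")

  # counts along the cascade are monotone non-increasing
  cnt <- glance(coh)
  expect_true(cnt$n_input_subjects >= cnt$n_diabetes &&
                cnt$n_diabetes >= cnt$n_with_baseline &&
                cnt$n_with_baseline >= cnt$n_final)

  # no creatinine anywhere
  nocr <- make_visits("nocr", 2000:2005, serum_creatinine = NA)
  coh2 <- assemble_cohort(dplyr::bind_rows(ok, nocr))
  expect_identical(tidy(coh2)$reason, "no_baseline_egfr")
})

test_that("all-eligible input passes through untouched and assembly is idempotent", {
  v <- dplyr::bind_rows(make_visits("A", 2000:2005),
                        make_visits("B", 2001:2007))
  coh <- assemble_cohort(v)
  expect_identical(glance(coh)$n_final, 2L)

  again <- assemble_cohort(coh$visits)
  expect_identical(again$visits, coh$visits)
  expect_identical(again$baselines, coh$baselines)
})

test_that("diabetes is anchored at baseline, not at later visits", {
  v <- make_visits("late", 2000:2005, hba1c = c(6.0, 6.0, 6.0, 8.0, 8.0, 8.0),
                   fasting_glucose = 6.0)
  coh <- assemble_cohort(v)
  expect_identical(glance(coh)$n_final, 0L)
  expect_identical(tidy(coh)$reason, "not_diabetic")

  # baseline labs missing: falls back to the most recent earlier visit
  v2 <- make_visits("fb", 2000:2006,
                    hba1c = c(8.0, NA, NA, NA, NA, NA, NA),
                    fasting_glucose = NA, on_dm_treatment = NA)
  v2$serum_creatinine[1] <- NA # baseline becomes 2001
  expect_identical(select_baseline(v2)$baseline_year, 2001L)
  expect_identical(glance(assemble_cohort(v2))$n_final, 1L)
})

test_that("n_final is what first-principles screening predicts on random cohorts", {
  # The reason ordering affects attribution only; the eligible set must
  # equal the subjects independently satisfying all three criteria.
  p <- cohort_profile(n_subjects = 300, seed = 427,
                      prop_retinopathy_missing = 0.1)
  v <- simulate_cohort(p)
  # knock out some records to create variety
  withr::with_seed(4271, {
    drop <- sample(nrow(v), 250)
    v2 <- v[-drop, ]
    nocr <- sample(nrow(v2), 100)
    v2$serum_creatinine[nocr] <- NA
  })
  coh <- assemble_cohort(v2)

  expected <- v2 |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(
      bl = {
        cr <- year[!is.na(serum_creatinine)]
        ok <- cr[max(year) - cr >= 5 & cr < max(year)]
        if (length(ok)) min(ok) else NA_integer_
      },
      fup = !is.na(bl) && any(!is.na(serum_creatinine) & year > bl &
                                year <= bl + 5),
      dm = {
        anchor <- if (is.na(bl)) min(year) else bl
        i <- which(year <= anchor & (!is.na(hba1c) |
                                       !is.na(fasting_glucose) |
                                       !is.na(on_dm_treatment)))
        if (!length(i)) FALSE else {
          j <- max(i)
          isTRUE(hba1c[j] >= 6.5) | isTRUE(fasting_glucose[j] >= 7) |
            isTRUE(on_dm_treatment[j])
        }
      }
    )
  expect_identical(glance(coh)$n_final,
                   sum(expected$dm & !is.na(expected$bl) & expected$fup))
  expect_setequal(coh$baselines$subject_id,
                  expected$subject_id[expected$dm & !is.na(expected$bl) &
                                        expected$fup])
})
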