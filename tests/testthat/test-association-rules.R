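test_that("rule counting matches hand-traced contingency cells", {
  # 10 rows, 4 factor-present, 2 of those worsening, 3 worsening overall
  ex <- tibble::tibble(
    risk_x = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
               FALSE),
    outcome = c("worsening", "worsening", "stable", "stable", "worsening",
                rep("stable", 5))
  )
  expect_identical(
    count_rule(ex, "x", "presence_worsening"),
    c(n_all = 10L, n_antecedent = 4L, n_joint = 2L, n_consequent = 3L)
  )
  expect_identical(
    count_rule(ex, "x", "absence_stable"),
    c(n_all = 10L, n_antecedent = 6L, n_joint = 5L, n_consequent = 7L)
  )
  expect_identical(
    count_rule(ex[0, ], "x", "presence_worsening"),
    c(n_all = 0L, n_antecedent = 0L, n_joint = 0L, n_consequent = 0L)
  )
  # missing flags leave all four counts
  ex$risk_x[c(1, 5)] <- NA
  expect_identical(count_rule(ex, "x", "presence_worsening")[["n_all"]], 8L)
})

test_that("confidence, lift and significance follow the formulas", {
  s <- score_rule(c(n_all = 10, n_antecedent = 4, n_joint = 2,
                    n_consequent = 3))
  expect_equal(s$confidence, 0.5)
  expect_equal(s$lift, 0.5 / 0.3)
  expect_true(s$significant)

  # lift exactly 1 is not significant
  s1 <- score_rule(c(n_all = 10, n_antecedent = 4, n_joint = 4,
                     n_consequent = 10))
  expect_equal(s1$confidence, 1)
  expect_equal(s1$lift, 1)
  expect_false(s1$significant)

  # empty antecedent: undefined confidence, not significant
  s0 <- score_rule(c(n_all = 10, n_antecedent = 0, n_joint = 0,
                     n_consequent = 3))
  expect_true(is.na(s0$confidence))
  expect_true(is.na(s0$lift))
  expect_false(s0$significant)

  # zero consequent base rate: undefined lift
  sz <- score_rule(c(n_all = 10, n_antecedent = 4, n_joint = 0,
                     n_consequent = 0))
  expect_equal(sz$confidence, 0)
  expect_true(is.na(sz$lift))
  expect_false(sz$significant)
})

test_that("mined results agree exactly with the brute-force oracle", {
  withr::with_seed(431, {
    for (rep in 1:25) {
      ex <- random_exposure(sample(3:20, 1), factors = c("a", "b"))
      for (f in c("a", "b")) {
        for (rule in c("absence_stable", "presence_worsening")) {
          o <- oracle_rule(ex, f, rule)
          cnt <- count_rule(ex, f, rule)
          expect_identical(as.integer(cnt),
                           as.integer(unlist(o[1:4])), )
          sc <- score_rule(cnt)
          expect_equal(sc$confidence, o$confidence)
          expect_equal(sc$lift, o$lift)
          expect_identical(sc$significant, o$significant)
        }
      }
    }
  })
})

test_that("mine_rules emits the complete cross-product in stable order", {
  p <- cohort_profile(n_subjects = 600, seed = 432)
  ex <- build_exposure_table(
    assemble_cohort(simulate_cohort(p)),
    specs = risk_factor_specs(include_retinopathy = TRUE)
  )
  r <- mine_rules(ex, schemes = "risk4")
  # 4 strata x 16 rule factors x 2 directions
  expect_identical(nrow(r), 128L)
  expect_identical(unique(r$stratum),
                   c("low", "moderate", "high", "very_high"))
  # deterministic: same input, same table
  expect_identical(tibble::as_tibble(mine_rules(ex, schemes = "risk4")),
                   tibble::as_tibble(r))
  # every (stratum, factor, rule) appears exactly once
  expect_identical(anyDuplicated(r[, c("scheme", "stratum", "factor",
                                       "rule")]), 0L)
})

test_that("counting identities hold across mined cells", {
  p <- cohort_profile(n_subjects = 1200, seed = 433,
                      worsening_base_rate = 0.15)
  ex <- build_exposure_table(assemble_cohort(simulate_cohort(p)))
  r <- mine_rules(ex)

  wide <- tidyr::pivot_wider(
    r[, c("scheme", "stratum", "factor", "rule", "n_all", "n_antecedent",
          "n_joint", "n_consequent")],
    names_from = "rule",
    values_from = c("n_all", "n_antecedent", "n_joint", "n_consequent")
  )
  # antecedents of the two directions partition the complete cases
  expect_identical(wide$n_antecedent_absence_stable +
                     wide$n_antecedent_presence_worsening,
                   wide$n_all_absence_stable)
  # consequents are complements within each cell
  expect_identical(wide$n_consequent_absence_stable +
                     wide$n_consequent_presence_worsening,
                   wide$n_all_absence_stable)

  # stable confidence given absence + worsening fraction given absence = 1
  abs_rows <- r[r$rule == "absence_stable" & r$n_antecedent > 0, ]
  worsen_frac <- (abs_rows$n_antecedent - abs_rows$n_joint) /
    abs_rows$n_antecedent
  expect_equal(abs_rows$confidence + worsen_frac, rep(1, nrow(abs_rows)))

  # lift is symmetric in antecedent and consequent
  pres <- r[r$rule == "presence_worsening" & !is.na(r$lift), ]
  swapped <- pres$n_joint / pres$n_consequent /
    (pres$n_antecedent / pres$n_all)
  expect_equal(pres$lift, swapped)

  # aggregating strata reproduces the overall joint counts
  r4 <- r[r$scheme == "risk4" & r$rule == "presence_worsening", ]
  ov <- r[r$scheme == "overall" & r$rule == "presence_worsening", ]
  agg <- tapply(r4$n_joint, r4$factor, sum)
  expect_equal(as.numeric(agg[ov$factor]), as.numeric(ov$n_joint))
})

test_that("a strong simulated effect yields a significant worsening rule", {
  p <- cohort_profile(n_subjects = 5000, worsening_base_rate = 0.05,
                      effect_map = c(hba1c = 3.0), seed = 434)
  ex <- build_exposure_table(assemble_cohort(simulate_cohort(p)))
  r <- mine_rules(ex, schemes = "overall")
  cell <- r[r$factor == "hba1c" & r$rule == "presence_worsening", ]
  expect_true(cell$significant)
  expect_gt(cell$lift, 1.5)
})
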