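#' Baseline characteristics table
#'
#' Mean and standard deviation of each continuous analyte at baseline and
#' percentages for the categorical variables (sex, proteinuria >= 1+,
#' retinopathy, diabetes treatment), plus the analysed n.
#'
#' @param cohort A `dkd_cohort`.
#' @param sd_single How to report the SD of a single-subject cohort:
#'   `"NA"` (default) or `"zero"`.
#' @return A tibble with columns `variable`, `n`, `mean`, `sd`, `pct`,
#'   `formatted`.
#' @export
baseline_table <- function(cohort, sd_single = c("NA", "zero")) {
  sd_single <- match.arg(sd_single)
  base <- baseline_rows(cohort)
  n <- nrow(base)
  sd_fun <- function(x) {
    if (length(x[!is.na(x)]) < 2L) {
      if (sd_single == "zero" && length(x[!is.na(x)]) == 1L) 0 else NA_real_
    } else {
      stats::sd(x, na.rm = TRUE)
    }
  }
  cont_vars <- c("age", "egfr", "hba1c", "fasting_glucose", "hemoglobin",
                 "ast", "alt", "ggt", "total_chol", "triglyceride", "hdl",
                 "ldl", "sbp", "dbp", "bmi")
  cont <- purrr::map_dfr(cont_vars, function(v) {
    x <- base[[v]]
    tibble::tibble(variable = v, n = sum(!is.na(x)),
                   mean = if (n) mean(x, na.rm = TRUE) else NA_real_,
                   sd = if (n) sd_fun(x) else NA_real_, pct = NA_real_)
  })
  pct <- function(x) if (n) 100 * mean(x, na.rm = TRUE) else NA_real_
  cat_ <- tibble::tibble(
    variable = c("sex_male", "urine_protein_ge1plus", "retinopathy",
                 "on_dm_treatment"),
    n = n, mean = NA_real_, sd = NA_real_,
    pct = c(pct(base$sex == "male"),
            pct(base$dipstick_protein %in% c("1+", "2+", "3+")),
            pct(base$retinopathy), pct(base$on_dm_treatment))
  )
  dplyr::bind_rows(cont, cat_) |>
    dplyr::mutate(formatted = dplyr::if_else(
      is.na(.data$pct),
      sprintf("%.1f ± %.1f", .data$mean, .data$sd),
      sprintf("%.1f%%", .data$pct)
    ))
}

#' Write rule results as tidy CSV
#'
#' Every cell of the mined cross-product appears exactly once; undefined
#' confidences and lifts are written as empty fields.
#'
#' @param rules A `dkd_rules` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rules_csv <- function(rules, path) {
  readr::write_csv(tibble::as_tibble(rules), path, na = "")
  invisible(path)
}

pipeline_defaults <- function() {
  list(
    cohort = "general",
    followup_years = 5,
    percentile = 20,
    include_retinopathy_factor = FALSE,
    schemes = c("overall", "risk4", "risk2_retinopathy",
                "risk2_retinopathy_slope"),
    figures = FALSE,
    figure_format = "png"
  )
}

#' Run the full analysis pipeline
#'
#' simulate (or read) -> assemble -> classify outcomes -> threshold and
#' binarize -> stage -> mine rules -> report. Writes, under
#' `output_dir`: `cohort.csv` (when simulated), `eligibility_report.json`,
#' `baseline_table.csv`, `thresholds.csv`, `exposure.csv`,
#' `outcomes.csv`, `rules.csv`, optional bubble-grid figures, and
#' `manifest.json` (resolved configuration, seed, package version, file
#' checksums). End-to-end deterministic given the configuration: the same
#' config produces byte-identical CSVs. On failure the stage name is
#' reported and partial outputs are removed.
#'
#' @param config A named list or the path of a YAML file. Keys:
#'   `profile` (list of [cohort_profile()] arguments, or the string
#'   `"general"`/`"worker"` for the ready-made profiles) or `input_csv`;
#'   `cohort` (kind, defaults to the profile's), `followup_years`,
#'   `percentile` (20 or 10), `schemes`, `include_retinopathy_factor`,
#'   `figures`, `figure_format`, `output_dir`, `seed` (overrides the
#'   profile seed).
#' @param output_dir Output directory; overrides `config$output_dir`.
#' @return Invisibly, a list with the in-memory objects (`cohort`,
#'   `exposure`, `rules`, `baseline_table`) and the written `paths`.
#' @examples
#' \donttest{
#' out <- run_pipeline(list(profile = list(n_subjects = 300, seed = 9),
#'                          schemes = "overall",
#'                          output_dir = tempfile()))
#' glance(out$rules)
#' }
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(pipeline_defaults(), config)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  if (is.null(cfg$output_dir)) stop("`output_dir` is required", call. = FALSE)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  written <- function(p) { paths <<- c(paths, p); p }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(paths)
      stop("pipeline stage `", name, "`: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  visits <- stage("input", {
    if (!is.null(cfg$input_csv)) {
      read_cohort_csv(cfg$input_csv)
    } else {
      prof <- cfg$profile
      if (is.character(prof)) {
        prof <- switch(prof, general = general_profile(),
                       worker = worker_profile(),
                       stop("unknown profile `", prof, "`"))
      } else if (is.list(prof) && !inherits(prof, "cohort_profile")) {
        prof <- do.call(cohort_profile, prof)
      } else if (is.null(prof)) {
        prof <- general_profile()
      }
      if (!is.null(cfg$seed)) prof$seed <- as.integer(cfg$seed)
      cfg$cohort <- cfg$cohort %||% prof$cohort_kind
      cfg$resolved_profile <- unclass(prof)[setdiff(names(prof),
                                                    "marginal_params")]
      v <- simulate_cohort(prof)
      write_cohort_csv(v, written(file.path(cfg$output_dir, "cohort.csv")))
      v
    }
  })

  cohort <- stage("assemble", {
    assemble_cohort(visits, cfg$cohort, cfg$followup_years)
  })
  stage("eligibility_report", {
    jsonlite::write_json(
      list(counts = cohort$report$counts,
           exclusions = cohort$report$exclusions),
      written(file.path(cfg$output_dir, "eligibility_report.json")),
      dataframe = "columns", pretty = TRUE
    )
  })

  exposure <- stage("exposure", {
    specs <- risk_factor_specs(cfg$percentile,
                               cfg$include_retinopathy_factor)
    build_exposure_table(cohort, cfg$percentile, specs)
  })
  stage("tables", {
    readr::write_csv(baseline_table(cohort),
                     written(file.path(cfg$output_dir,
                                       "baseline_table.csv")), na = "")
    readr::write_csv(attr(exposure, "thresholds"),
                     written(file.path(cfg$output_dir, "thresholds.csv")),
                     na = "")
    readr::write_csv(tibble::as_tibble(exposure),
                     written(file.path(cfg$output_dir, "exposure.csv")),
                     na = "")
    readr::write_csv(renal_outcomes(cohort),
                     written(file.path(cfg$output_dir, "outcomes.csv")),
                     na = "")
  })

  rules <- stage("mine", {
    r <- mine_rules(exposure, schemes = cfg$schemes)
    write_rules_csv(r, written(file.path(cfg$output_dir, "rules.csv")))
    r
  })

  if (isTRUE(cfg$figures)) {
    stage("figures", {
      dev_ok <- cfg$figure_format %in% c("png", "pdf") &&
        (cfg$figure_format != "png" || capabilities("png"))
      fmt <- if (dev_ok) cfg$figure_format else "pdf"
      for (sc in cfg$schemes) {
        f <- written(file.path(cfg$output_dir,
                               paste0("rules_", sc, ".", fmt)))
        ggplot2::ggsave(f, plot_rule_grid(rules, sc),
                        width = 12, height = 6, dpi = 150)
      }
    })
  }

  stage("manifest", {
    csvs <- paths[grepl("\\.csv$", paths)]
    jsonlite::write_json(
      list(
        config = cfg[setdiff(names(cfg), "profile")],
        package_version = as.character(utils::packageVersion("dkdrules")),
        r_version = R.version.string,
        md5 = as.list(tools::md5sum(csvs))
      ),
      written(file.path(cfg$output_dir, "manifest.json")),
      auto_unbox = TRUE, pretty = TRUE, null = "null", force = TRUE
    )
  })

  invisible(list(cohort = cohort, exposure = exposure, rules = rules,
                 baseline_table = baseline_table(cohort), paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
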