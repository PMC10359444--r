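#' Cohort CSV schema
#'
#' One row per subject-visit; one header row, UTF-8, integer examination
#' years, missing values encoded as empty cells. `dipstick_protein` takes
#' the grades `negative`, `trace`, `1+`, `2+`, `3+`; `sex` is `male` or
#' `female`; the three flag columns are logical. `eskd_event` is only
#' meaningful for worker cohorts and defaults to `FALSE`.
#'
#' @return A tibble with columns `column` and `type` (`c`haracter,
#'   `i`nteger, `d`ouble, `l`ogical).
#' @export
cohort_schema <- function() {
  tibble::tibble(
    column = c("subject_id", "year", "age", "sex", "serum_creatinine",
               "dipstick_protein", "hba1c", "fasting_glucose", "hemoglobin",
               "ast", "alt", "ggt", "total_chol", "triglyceride", "hdl",
               "ldl", "sbp", "dbp", "bmi", "retinopathy", "on_dm_treatment",
               "eskd_event"),
    type = c("c", "i", "d", "c", "d",
             "c", "d", "d", "d",
             "d", "d", "d", "d", "d", "d",
             "d", "d", "d", "d", "l", "l",
             "l")
  )
}

dipstick_grades <- function() c("negative", "trace", "1+", "2+", "3+")

#' Validate a table of visit records
#'
#' Checks the cohort schema and the record invariants: all schema columns
#' present and no unknown ones, positive serum creatinine, age and lab
#' values where present, known dipstick grades and sex codes, and distinct
#' years within subject. Errors name the first offending row and column.
#'
#' @param visits A data frame of visit records.
#' @return The input as a tibble, invisibly valid.
#' @export
validate_cohort <- function(visits) {
  visits <- tibble::as_tibble(visits)
  sch <- cohort_schema()
  unknown <- setdiff(names(visits), sch$column)
  if (length(unknown)) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(sch$column, names(visits))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  visits <- visits[, sch$column]
  fail <- function(col, bad) {
    if (any(bad, na.rm = TRUE)) {
      stop("row ", which(bad)[1], ": invalid value in column `", col, "`",
           call. = FALSE)
    }
  }
  fail("serum_creatinine", visits$serum_creatinine <= 0)
  fail("age", visits$age <= 0)
  for (col in c("hba1c", "fasting_glucose", "hemoglobin", "ast", "alt",
                "ggt", "total_chol", "triglyceride", "hdl", "ldl", "sbp",
                "dbp", "bmi")) {
    fail(col, visits[[col]] <= 0)
  }
  fail("sex", !visits$sex %in% c("male", "female"))
  fail("dipstick_protein",
       !is.na(visits$dipstick_protein) &
         !visits$dipstick_protein %in% dipstick_grades())
  dup <- duplicated(visits[, c("subject_id", "year")])
  if (any(dup)) {
    stop("row ", which(dup)[1], ": duplicate (subject_id, year) pair `",
         visits$subject_id[which(dup)[1]], "`, ",
         visits$year[which(dup)[1]], call. = FALSE)
  }
  visits
}

#' Read and write cohort CSV files
#'
#' `write_cohort_csv()` validates and writes visit records;
#' `read_cohort_csv()` reads and validates them. The pair round-trips
#' field-for-field (doubles are written with shortest round-trippable
#' representation). Unparseable numerics, unknown columns, invariant
#' violations and duplicate (subject, year) pairs raise errors naming the
#' row and column.
#'
#' @param visits Visit records (see [cohort_schema()]).
#' @param path File path.
#' @return `read_cohort_csv()` returns a tibble of visit records;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
write_cohort_csv <- function(visits, path) {
  visits <- validate_cohort(visits)
  readr::write_csv(visits, path, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  sch <- cohort_schema()
  spec <- do.call(readr::cols_only,
                  stats::setNames(as.list(sch$type), sch$column))
  x <- readr::read_csv(path, col_types = spec, na = "",
                       progress = FALSE, lazy = FALSE)
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               progress = FALSE))
  unknown <- setdiff(hdr, sch$column)
  if (length(unknown)) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pb <- readr::problems(x)
  if (nrow(pb)) {
    stop("row ", pb$row[1], ": cannot parse column `",
         if (is.numeric(pb$col)) hdr[pb$col[1]] else pb$col[1],
         "` (", pb$expected[1], ")", call. = FALSE)
  }
  validate_cohort(x)
}
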