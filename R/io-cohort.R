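#' Cohort table schema
#'
#' The cohort table carries one row per subject with demographics, vascular
#' and lifestyle risk factors, drug-use indicators, genotype allele counts
#' and, once computed, the derived indices (`spare_ba`, `spare_ad`,
#' `z_residual`, `group_label`, `pgs`). Categorical columns are restricted to
#' fixed level sets; the derived columns are optional on read.
#'
#' Levels: `sex` male/female; `smoking` never/former/current; `education`
#' `<8`, `8-10`, `>10` (years of schooling); `physical_activity` none/low/
#' moderate/high.
#'
#' @return Named list of allowed levels per categorical column.
#' @export
cohort_levels <- function() {
  list(
    sex               = c("male", "female"),
    smoking           = c("never", "former", "current"),
    education         = c("<8", "8-10", ">10"),
    physical_activity = c("none", "low", "moderate", "high")
  )
}

cohort_numeric_cols <- c("age", "systolic_bp", "hba1c", "waist")
cohort_binary_cols  <- c("antihypertensive", "antidiabetic", "antidepressant")

#' Validate a cohort table against the schema
#'
#' Checks required columns, categorical level sets, binary indicators and
#' genotype allele counts; violations raise a validation error naming the
#' offending rows. Derived index columns are optional.
#'
#' @param table a data frame.
#' @return The table, invisibly, as a tibble with categorical columns as
#'   factors on the documented levels.
#' @export
validate_cohort <- function(table) {
  table <- as_tibble(table)
  required <- c("subject_id", "age", "sex")
  miss <- setdiff(required, names(table))
  if (length(miss)) abort(paste("missing required columns:", paste(miss, collapse = ", ")),
                          class = "spareatlas_validation_error")
  if (anyDuplicated(table$subject_id))
    abort("duplicated subject_id", class = "spareatlas_validation_error")
  for (col in intersect(names(cohort_levels()), names(table))) {
    lv <- cohort_levels()[[col]]
    vals <- as.character(table[[col]])
    bad <- which(!is.na(vals) & !vals %in% lv)
    if (length(bad))
      abort(sprintf("column '%s' has unknown level(s) %s in row(s) %s",
                    col, paste(unique(vals[bad]), collapse = ", "),
                    paste(head(bad, 10), collapse = ", ")),
            class = "spareatlas_validation_error")
    table[[col]] <- factor(vals, levels = lv)
  }
  for (col in intersect(cohort_binary_cols, names(table))) {
    bad <- which(!is.na(table[[col]]) & !table[[col]] %in% c(0, 1))
    if (length(bad))
      abort(sprintf("column '%s' must be 0/1; bad row(s) %s", col,
                    paste(head(bad, 10), collapse = ", ")),
            class = "spareatlas_validation_error")
  }
  snp_cols <- grep("^snp_", names(table), value = TRUE)
  for (col in snp_cols) {
    bad <- which(!is.na(table[[col]]) & !table[[col]] %in% c(0, 1, 2))
    if (length(bad))
      abort(sprintf("allele count column '%s' outside {0,1,2}; bad row(s) %s", col,
                    paste(head(bad, 10), collapse = ", ")),
            class = "spareatlas_validation_error")
  }
  invisible(table)
}

#' Read or write a cohort table as CSV
#'
#' Plain UTF-8, RFC-4180 CSV with a header row. Reading applies the schema
#' validation of [validate_cohort()]; derived columns absent from the file are
#' simply absent from the result.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_cohort <- function(path) {
  table <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(table)
  # re-run to also return the factor-coerced copy
  out <- validate_cohort(table)
  out
}

#' @rdname read_cohort
#' @param table a cohort table (validated before writing).
#' @export
write_cohort <- function(table, path) {
  validate_cohort(table)
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

check_maps_match_table <- function(maps, table) {
  if (!setequal(maps$subject_id, table$subject_id) ||
      length(maps$subject_id) != nrow(table))
    abort("map subject ids and cohort table rows do not match 1:1",
          class = "spareatlas_validation_error")
  invisible(TRUE)
}
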