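#' Default covariate set for the index risk-factor model
#'
#' The multivariable model relates an atrophy index to vascular and lifestyle
#' risk factors: age and a quadratic age term (age is centered before
#' squaring to limit collinearity; other estimates are unaffected), systolic
#' blood pressure, HbA1c, smoking status (reference: never), waist
#' circumference, education (reference: <8 years), physical activity
#' (reference: none) and the three drug-use indicators. Models are typically
#' fitted separately by sex.
#'
#' @return Character vector of covariate terms understood by
#'   [fit_index_model()].
#' @export
default_covariates <- function() {
  c("age", "age_sq", "systolic_bp", "hba1c", "smoking", "waist",
    "education", "physical_activity", "antihypertensive", "antidiabetic",
    "antidepressant")
}

build_design_data <- function(table, outcome, covariates) {
  cols <- setdiff(covariates, "age_sq")
  miss <- setdiff(c(outcome, cols), names(table))
  if (length(miss))
    abort(paste("missing column(s):", paste(miss, collapse = ", ")),
          class = "spareatlas_validation_error")
  dat <- table[, intersect(unique(c("subject_id", outcome, cols)), names(table)),
               drop = FALSE]
  if ("age_sq" %in% covariates) dat$age_sq <- (dat$age - mean(dat$age, na.rm = TRUE))^2
  for (col in intersect(names(cohort_levels()), names(dat)))
    dat[[col]] <- factor(as.character(dat[[col]]), levels = cohort_levels()[[col]])
  dat
}

fit_one_stratum <- function(dat, outcome, covariates, stratum = NA_character_) {
  keep <- complete.cases(dat[, c(outcome, covariates), drop = FALSE])
  dropped <- sum(!keep)
  if (dropped > 0)
    inform(sprintf("dropping %d row(s) with missing model data%s", dropped,
                   if (is.na(stratum)) "" else paste0(" in stratum ", stratum)))
  dat <- dat[keep, , drop = FALSE]
  dat <- droplevels(dat)
  form <- as.formula(paste(outcome, "~", paste(covariates, collapse = " + ")))
  n_par <- ncol(model.matrix(form, dat))
  if (nrow(dat) < n_par + 2)
    abort(sprintf("stratum %s has %d usable rows for %d parameters", stratum,
                  nrow(dat), n_par),
          class = "spareatlas_validation_error")
  fit <- lm(form, data = dat)
  if (any(is.na(coef(fit)))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    abort(paste("rank-deficient design; aliased term(s):",
                paste(aliased, collapse = ", ")),
          class = "spareatlas_validation_error")
  }
  structure(list(fit = fit, outcome = outcome, covariates = covariates,
                 stratum = stratum, n = nrow(dat), n_dropped = dropped),
            class = "index_fit")
}

#' Fit the multivariable index risk-factor model, optionally by stratum
#'
#' Ordinary least squares with intercept; categorical covariates are
#' dummy-coded against their documented reference levels, rows with missing
#' model data are dropped listwise (with a message reporting the count), and
#' a rank-deficient design raises an error naming the aliased terms. With
#' `strata` (default `"sex"`), one model is fitted independently per stratum
#' level.
#'
#' @param table cohort tibble.
#' @param outcome outcome column name (e.g. `"spare_ba"`).
#' @param covariates covariate terms; `"age_sq"` expands to centered
#'   age squared. Defaults to [default_covariates()].
#' @param strata stratification column name, or `NULL` for a single model.
#' @return An `index_fit_set`: named list of `index_fit` objects with
#'   [tidy()] and [glance()] methods.
#' @examples
#' \dontrun{
#' fit_index_model(cohort$table, "spare_ba") |> tidy()
#' }
#' @export
fit_index_model <- function(table, outcome, covariates = default_covariates(),
                            strata = "sex") {
  dat <- build_design_data(table, outcome, covariates)
  if (is.null(strata)) {
    fits <- list(all = fit_one_stratum(dat, outcome, covariates, "all"))
  } else {
    if (!strata %in% names(table))
      abort(paste("no stratification column", strata), class = "spareatlas_validation_error")
    dat$.stratum <- table[[strata]]  # row order preserved by build_design_data
    groups <- split(dat, dat$.stratum, drop = TRUE)
    if (!length(groups)) abort("all strata empty", class = "spareatlas_validation_error")
    fits <- purrr::imap(groups, function(d, s) fit_one_stratum(d, outcome, covariates, s))
  }
  structure(fits, class = "index_fit_set")
}

#' @export
print.index_fit_set <- function(x, ...) {
  cat(sprintf("<index_fit_set> %d stratum model(s): %s\n", length(x),
              paste(names(x), collapse = ", ")))
  print(glance(x))
  invisible(x)
}

#' @export
tidy.index_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(stratum = x$stratum, term = rownames(sm),
         estimate = unname(sm[, 1]), std_error = unname(sm[, 2]),
         statistic = unname(sm[, 3]), p_value = unname(sm[, 4]))
}

#' @export
glance.index_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble(stratum = x$stratum, r_squared = sm$r.squared,
         adj_r_squared = sm$adj.r.squared, n = x$n, n_dropped = x$n_dropped)
}

#' @export
tidy.index_fit_set <- function(x, ...) dplyr::bind_rows(lapply(x, tidy))

#' @export
glance.index_fit_set <- function(x, ...) dplyr::bind_rows(lapply(x, glance))

#' Pearson correlation with a t-based p-value
#'
#' @param x,y numeric vectors (at least 3 complete pairs, both with positive
#'   variance).
#' @return One-row tibble with `r`, `p`, `n`, `df`.
#' @export
pearson_with_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) abort("need at least 3 complete pairs", class = "spareatlas_validation_error")
  if (var(x[ok]) == 0 || var(y[ok]) == 0)
    abort("zero variance", class = "spareatlas_validation_error")
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value,
         n = sum(ok), df = unname(ct$parameter))
}

#' Two-group pooled-variance Student t-test with group summaries
#'
#' @param values_a,values_b numeric vectors, at least 2 each.
#' @return One-row tibble with `t`, `df`, `p`, and each group's mean, sd and
#'   n.
#' @export
group_mean_test <- function(values_a, values_b) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2)
    abort("each group needs at least 2 values", class = "spareatlas_validation_error")
  sp2 <- ((length(values_a) - 1) * var(values_a) +
          (length(values_b) - 1) * var(values_b)) /
         (length(values_a) + length(values_b) - 2)
  if (sp2 == 0) abort("zero pooled variance", class = "spareatlas_validation_error")
  tt <- t.test(values_a, values_b, var.equal = TRUE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
         mean_a = mean(values_a), sd_a = sd(values_a), n_a = length(values_a),
         mean_b = mean(values_b), sd_b = sd(values_b), n_b = length(values_b))
}

#' Adjusted association between an outcome and one predictor
#'
#' OLS of the outcome on the predictor plus adjuster columns (listwise
#' deletion, message with the dropped count); reports the predictor's
#' coefficient, its standard error and two-sided p — the form used for, e.g.,
#' polygenic-score or cognitive-score associations adjusted for age, sex and
#' education.
#'
#' @param table data frame.
#' @param outcome,predictor column names.
#' @param adjusters character vector of adjuster column names (may be empty).
#' @return One-row tibble with `predictor`, `estimate`, `std_error`,
#'   `statistic`, `p_value`, `n`.
#' @export
outcome_adjusted_association <- function(table, outcome, predictor,
                                         adjusters = character()) {
  dat <- build_design_data(table, outcome, c(predictor, adjusters))
  fit <- fit_one_stratum(dat, outcome, c(predictor, adjusters), "all")
  co <- tidy(fit)
  row <- co[grepl(paste0("^", predictor), co$term), , drop = FALSE][1, ]
  tibble(predictor = predictor, estimate = row$estimate,
         std_error = row$std_error, statistic = row$statistic,
         p_value = row$p_value, n = fit$n)
}
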