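#' Age-residualize an index score
#'
#' Fits a simple OLS regression of the score on age, takes residuals, and
#' z-standardizes them with the sample standard deviation (denominator
#' n - 1). Deviation from the age trend — not the raw score — defines who is
#' aging faster or slower than expected.
#'
#' @param scores numeric index values.
#' @param ages ages in years.
#' @return List with `residuals`, `z` and `fit` (intercept, slope).
#' @export
residualize_on_age <- function(scores, ages) {
  ok <- is.finite(scores) & is.finite(ages)
  if (sum(ok) < 3) abort("need at least 3 subjects", class = "spareatlas_validation_error")
  if (var(ages[ok]) == 0) abort("zero age variance", class = "spareatlas_validation_error")
  fit <- lm.fit(cbind(1, ages[ok]), scores[ok])
  res <- rep(NA_real_, length(scores))
  res[ok] <- fit$residuals
  s <- sd(fit$residuals)
  if (s <= 1e-10 * max(1, sd(scores[ok])))
    abort("zero residual variance (scores collinear with age)",
          class = "spareatlas_validation_error")
  list(residuals = res,
       z = (res - mean(fit$residuals)) / s,
       fit = list(intercept = unname(fit$coefficients[1]),
                  slope = unname(fit$coefficients[2])))
}

#' Assign extreme-deviation group labels from z-scores
#'
#' Strict inequalities on both sides: `z < -threshold` gets `label_low`,
#' `z > threshold` gets `label_high`, everything else (including exact
#' threshold ties) stays `"unassigned"`. For the brain-aging index the low
#' tail is the advanced-brain-aging (ABA) group and the high tail the
#' resilient (RA) group.
#'
#' @param z standardized age residuals.
#' @param threshold positive z cutoff (default 0.5).
#' @param label_low,label_high labels for the two tails.
#' @return Factor with levels `label_low`, `label_high`, `"unassigned"`;
#'   missing z gives NA.
#' @export
assign_groups <- function(z, threshold = 0.5, label_low = "ABA", label_high = "RA") {
  if (threshold <= 0) abort("threshold must be positive", class = "spareatlas_config_error")
  lab <- ifelse(z < -threshold, label_low,
                ifelse(z > threshold, label_high, "unassigned"))
  factor(lab, levels = c(label_low, label_high, "unassigned"))
}

#' Age-eligibility filter
#'
#' Subjects at or above the age floor (inclusive), the subset in which the
#' aging groups are defined — clinical AD prevalence rises substantially
#' after 65, which motivates the default.
#'
#' @param table cohort tibble.
#' @param age_floor years (default 65).
#' @return Character vector of eligible subject ids.
#' @export
age_filter <- function(table, age_floor = 65) {
  table$subject_id[!is.na(table$age) & table$age >= age_floor]
}

#' Label extreme aging groups in a cohort table
#'
#' Pipe-friendly wrapper over [age_filter()], [residualize_on_age()] and
#' [assign_groups()]: restricts to subjects at or above `age_floor`, fits the
#' age regression and the z-transform within that subset (optionally on all
#' ages via `fit_all_ages`), and writes `z_residual` and `group_label`
#' columns (`NA` outside the eligible subset).
#'
#' @param table cohort tibble.
#' @param score_col name of the index column (default `"spare_ba"`).
#' @param age_floor,threshold see [age_filter()] and [assign_groups()].
#' @param label_low,label_high tail labels (defaults ABA / RA; use e.g.
#'   `"LOW_AD"` / `"HIGH_AD"` for an AD-index split).
#' @param fit_all_ages fit the age regression on the full table instead of
#'   the eligible subset.
#' @param z_col,label_col output column names.
#' @return The table with z-scores and labels added.
#' @export
label_aging_groups <- function(table, score_col = "spare_ba", age_floor = 65,
                               threshold = 0.5, label_low = "ABA",
                               label_high = "RA", fit_all_ages = FALSE,
                               z_col = "z_residual", label_col = "group_label") {
  if (!score_col %in% names(table))
    abort(paste("no column", score_col), class = "spareatlas_validation_error")
  eligible <- table$subject_id %in% age_filter(table, age_floor)
  fit_rows <- if (fit_all_ages) rep(TRUE, nrow(table)) else eligible
  rz <- residualize_on_age(table[[score_col]][fit_rows], table$age[fit_rows])
  z <- rep(NA_real_, nrow(table))
  if (fit_all_ages) {
    # regression fitted on everyone; z restricted to the eligible subset
    res <- table[[score_col]] - (rz$fit$intercept + rz$fit$slope * table$age)
    z[eligible] <- (res[eligible] - mean(res[eligible], na.rm = TRUE)) /
      sd(res[eligible], na.rm = TRUE)
  } else {
    z[fit_rows] <- rz$z
  }
  table[[z_col]] <- z
  lab <- rep(NA_character_, nrow(table))
  lab[eligible] <- as.character(assign_groups(z[eligible], threshold,
                                              label_low, label_high))
  table[[label_col]] <- factor(lab, levels = c(label_low, label_high, "unassigned"))
  table
}
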