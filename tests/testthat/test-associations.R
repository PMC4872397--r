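cohort_table <- function(n = 120, seed = 3) {
  co <- generate_cohort(tiny_config(n = n, grid = c(4, 4, 4), seed = seed))
  co$table
}

test_that("a noiseless linear outcome fits with R-squared 1", {
  tab <- cohort_table()
  tab$y <- 2 - 0.05 * tab$age + 0.3 * (tab$smoking == "current") + 0.01 * tab$waist
  fit <- fit_index_model(tab, "y", covariates = c("age", "smoking", "waist"),
                         strata = NULL)
  expect_equal(suppressWarnings(glance(fit)$r_squared), 1, tolerance = 1e-10)
  td <- suppressWarnings(tidy(fit))  # "essentially perfect fit" is the point here
  expect_equal(td$estimate[td$term == "age"], -0.05, tolerance = 1e-8)
})

test_that("stratified fits match an independent normal-equations solver", {
  tab <- cohort_table(n = 150)
  set.seed(4)
  tab$y <- 1 - 0.03 * tab$age + 0.2 * tab$antihypertensive + rnorm(150, sd = 0.5)
  fits <- fit_index_model(tab, "y", covariates = c("age", "antihypertensive"))
  expect_named(fits, c("male", "female"))
  for (s in names(fits)) {
    sub <- tab[tab$sex == s, ]
    X <- cbind(1, sub$age, sub$antihypertensive)
    orc <- oracle_ols(X, sub$y)
    td <- tidy(fits[[s]])
    expect_equal(td$estimate, orc$beta, tolerance = 1e-8)
    expect_equal(td$std_error, unname(orc$se), tolerance = 1e-8)
    expect_equal(td$p_value, unname(orc$p), tolerance = 1e-8)
  }
})

test_that("full default model runs with quadratic age and reference coding", {
  tab <- cohort_table(n = 200, seed = 9)
  set.seed(1)
  tab$spare_ba <- 5 - 0.1 * tab$age + rnorm(200, sd = 0.4)
  fits <- fit_index_model(tab, "spare_ba")
  td <- tidy(fits)
  expect_true("age_sq" %in% td$term)
  expect_true(all(c("smokingformer", "smokingcurrent") %in% td$term))  # never = ref
  expect_false(any(grepl("smokingnever", td$term)))
  expect_true(all(td$p_value >= 0 & td$p_value <= 1))
})

test_that("model preconditions are enforced", {
  tab <- cohort_table(n = 40)
  tab$y <- rnorm(40)
  tab$dup <- tab$age
  expect_error(fit_index_model(tab, "y", covariates = c("age", "dup"), strata = NULL),
               regexp = "aliased", class = "spareatlas_validation_error")
  expect_error(fit_index_model(tab[1:5, ], "y", strata = NULL),
               class = "spareatlas_validation_error")
  expect_error(fit_index_model(tab, "nope", strata = NULL),
               class = "spareatlas_validation_error")
  tab$age[1:6] <- NA
  expect_message(fit_index_model(tab, "y", covariates = c("age", "waist"),
                                 strata = NULL), "dropping 6")
})

test_that("coefficient p-values are uniform when the outcome is permuted", {
  tab <- cohort_table(n = 60, seed = 21)
  set.seed(33)
  base <- rnorm(60)
  pvals <- replicate(200, {
    tab$y <- sample(base)
    td <- tidy(fit_index_model(tab, "y", covariates = c("age", "waist"),
                               strata = NULL))
    td$p_value[td$term == "age"]
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("planted covariate effects on an atrophy index are recovered", {
  cfg <- tiny_config(n = 150, grid = c(8, 8, 8), seed = 41)
  co <- generate_cohort(cfg)
  dens <- region_density(co$maps, co$truth$aging_mask)
  tab <- co$table
  tab$aging_index <- dens$density
  fit <- fit_index_model(tab, "aging_index",
                         covariates = c("age", "smoking", "antihypertensive", "waist"),
                         strata = NULL)
  td <- tidy(fit)
  truth <- c(age = -cfg$aging_slope,
             smokingformer = -cfg$risk_effects[["smoking_former"]],
             smokingcurrent = -cfg$risk_effects[["smoking_current"]],
             antihypertensive = -cfg$risk_effects[["antihypertensive"]],
             waist = -cfg$risk_effects[["waist"]])
  for (term in names(truth)) {
    row <- td[td$term == term, ]
    expect_lt(abs(row$estimate - truth[[term]]), 3 * row$std_error)
  }
})

test_that("pearson_with_p matches the textbook formulas", {
  expect_equal(pearson_with_p(1:10, 1:10)$r, 1)
  expect_equal(pearson_with_p(1:10, -(1:10))$r, -1)
  x <- c(1.2, 3.4, 2.2, 5.6, 4.1)
  y <- c(0.7, 2.9, 1.1, 4.8, 4.4)
  got <- pearson_with_p(x, y)
  orc <- oracle_pearson(x, y)
  expect_equal(got$r, orc$r, tolerance = 1e-10)
  expect_equal(got$p, orc$p, tolerance = 1e-10)
  expect_error(pearson_with_p(c(1, 1, 1), 1:3), class = "spareatlas_validation_error")
  expect_error(pearson_with_p(1:2, 1:2), class = "spareatlas_validation_error")
})

test_that("group_mean_test reports pooled t with group summaries", {
  same <- c(1, 2, 3)
  out0 <- group_mean_test(same, same)
  expect_equal(out0$t, 0)
  expect_equal(out0$p, 1)
  out <- group_mean_test(c(1, 2, 3), c(4, 5, 6))
  orc <- oracle_pooled_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$t, orc$t, tolerance = 1e-10)
  expect_equal(out$p, orc$p, tolerance = 1e-10)
  expect_equal(out$mean_a, 2)
  expect_equal(out$sd_b, 1)
  expect_error(group_mean_test(c(1, 1), c(1, 1)), class = "spareatlas_validation_error")
})

test_that("a one-sd shift is detected in at least 95% of replicates at n = 50", {
  set.seed(55)
  hits <- replicate(100, {
    a <- rnorm(50)
    b <- rnorm(50, mean = 1)
    group_mean_test(a, b)$p < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("adjusted associations report the predictor coefficient", {
  tab <- cohort_table(n = 100, seed = 61)
  set.seed(8)
  tab$pgs <- rnorm(100)
  tab$outcome <- 0.5 * tab$pgs + 0.02 * tab$age + rnorm(100, sd = 0.3)
  out <- outcome_adjusted_association(tab, "outcome", "pgs", c("age", "sex"))
  expect_equal(out$predictor, "pgs")
  expect_lt(abs(out$estimate - 0.5), 3 * out$std_error)
  expect_lt(out$p_value, 1e-6)
  tab$pgs_copy <- tab$pgs  # adjuster collinear with the predictor
  expect_error(outcome_adjusted_association(tab, "outcome", "pgs", c("age", "pgs_copy")),
               class = "spareatlas_validation_error")
  # predictor independent of the outcome: p is null-distributed
  set.seed(9)
  pvals <- replicate(200, {
    tab$noise <- rnorm(100)
    outcome_adjusted_association(tab, "outcome", "noise", "age")$p_value
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})
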