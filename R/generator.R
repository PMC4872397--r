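#' Configuration for the synthetic cohort generator
#'
#' Describes a synthetic population of gray-matter volumetric maps with a
#' planted atrophy geometry. Each subject's noise-free map is
#'
#' \deqn{m(v) = b - s (a - a_{lo}) 1_{aging}(v) - \sum_k e_k x_k 1_{aging}(v)
#'             - d \, 1_{AD}(v) \, 1_{ad\_status}}
#'
#' where `b` is `baseline_gm`, `s` the `aging_slope` (density units lost per
#' year, applied inside the aging mask from the lower end of the age range),
#' `e_k` the `risk_effects` (density units lost per unit exposure, applied
#' inside the aging mask), and `d` the `ad_effect` (density units lost inside
#' the AD mask for AD-status subjects). i.i.d. Gaussian voxel noise of sd
#' `noise_sd` is added on top; `noise_smooth_sd > 0` optionally smooths the
#' noise field with a separable Gaussian kernel (voxel units), emulating
#' spatially correlated registration noise.
#'
#' The aging and AD masks must partially overlap: at least one shared voxel
#' and at least one voxel unique to each, so that downstream pattern-overlap
#' analyses have a non-trivial planted geometry.
#'
#' Risk-factor exposures and their planted effects (defaults): former smoking
#' 1.75 and current smoking 3.5 density units (vs never), anti-hypertensive
#' drug use 2.5 units, and 0.09 units per cm of waist circumference above
#' 90 cm — with the default aging slope these correspond to roughly 3 to 7
#' years of excess brain aging, sized so the planted between-group contrast
#' is detectable at the default cohort size. Covariates without planted
#' effects (blood pressure, HbA1c,
#' education, physical activity, anti-diabetic and anti-depressant use) are
#' still simulated so association models have realistic nuisance terms.
#'
#' `ad_fraction` plants the AD deficit in that expected fraction of cohort
#' subjects aged `ad_age_min` or older (emulating preclinical AD in the
#' elderly); when `pgs_coupling > 0` the per-subject probability follows a
#' logistic model in the standardized polygenic risk score, so genetic risk
#' and the AD atrophy pattern are coupled.
#'
#' @param n_subjects number of subjects (at least 4).
#' @param grid integer vector of length 3, voxel grid shape.
#' @param age_range `[lo, hi]` in years; ages are uniform over the range.
#' @param aging_mask,ad_mask [mask_box()]/[mask_sphere()] specs or logical
#'   arrays.
#' @param baseline_gm baseline gray-matter density (arbitrary units, > 0).
#' @param aging_slope density units lost per year inside the aging mask.
#' @param ad_effect density units lost inside the AD mask for AD subjects.
#' @param risk_effects named numeric vector of density-unit effects for
#'   `smoking_former`, `smoking_current`, `antihypertensive` and `waist`
#'   (per cm above 90).
#' @param noise_sd voxel noise standard deviation (density units, >= 0).
#' @param noise_smooth_sd Gaussian smoothing sd of the noise field in voxels
#'   (0 = independent noise).
#' @param snp_panel tibble with columns `snp_id`, `frequency`, `odds_ratio`
#'   (defaults to the 19-SNP example panel of [default_snp_panel()]).
#' @param ad_fraction expected fraction of subjects aged `>= ad_age_min`
#'   carrying the AD deficit (default 0: none).
#' @param ad_age_min minimum age for planted AD status, years.
#' @param pgs_coupling log-odds of AD status per sd of polygenic score.
#' @param seed integer RNG seed; identical configs generate identical cohorts.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 400,
                             grid = c(24L, 24L, 24L),
                             age_range = c(20, 90),
                             aging_mask = mask_sphere(c(11, 11, 11), 7),
                             ad_mask = mask_sphere(c(17, 11, 11), 4.5),
                             baseline_gm = 100,
                             aging_slope = 0.5,
                             ad_effect = 12,
                             risk_effects = c(smoking_former = 1.75,
                                              smoking_current = 3.5,
                                              antihypertensive = 2.5,
                                              waist = 0.09),
                             noise_sd = 1,
                             noise_smooth_sd = 0,
                             snp_panel = default_snp_panel(),
                             ad_fraction = 0,
                             ad_age_min = 65,
                             pgs_coupling = 1,
                             seed = 1L) {
  grid <- as.integer(grid)
  if (n_subjects < 4) abort("n_subjects must be at least 4 (two groups of two)",
                            class = "spareatlas_config_error")
  if (baseline_gm <= 0) abort("baseline_gm must be positive", class = "spareatlas_config_error")
  if (noise_sd < 0) abort("noise_sd must be non-negative", class = "spareatlas_config_error")
  if (age_range[2] <= age_range[1]) abort("age_range must be increasing", class = "spareatlas_config_error")
  if (any(snp_panel$frequency <= 0 | snp_panel$frequency >= 1))
    abort("allele frequencies must lie in (0,1)", class = "spareatlas_config_error")
  if (any(snp_panel$odds_ratio <= 0))
    abort("odds ratios must be positive", class = "spareatlas_config_error")
  aging <- resolve_mask(aging_mask, grid)
  ad <- resolve_mask(ad_mask, grid)
  if (!any(aging & ad) || !any(aging & !ad) || !any(ad & !aging))
    abort("aging and AD masks must partially overlap (shared voxels plus voxels unique to each)",
          class = "spareatlas_config_error")
  structure(list(n_subjects = as.integer(n_subjects), grid = grid,
                 age_range = as.numeric(age_range),
                 aging_mask = aging, ad_mask = ad,
                 baseline_gm = baseline_gm, aging_slope = aging_slope,
                 ad_effect = ad_effect, risk_effects = risk_effects,
                 noise_sd = noise_sd, noise_smooth_sd = noise_smooth_sd,
                 snp_panel = snp_panel,
                 ad_fraction = ad_fraction, ad_age_min = ad_age_min,
                 pgs_coupling = pgs_coupling, seed = as.integer(seed)),
            class = "generator_config")
}

# separable Gaussian smoothing of a 3D array (kernel truncated at 3 sd)
smooth_gaussian_3d <- function(arr, sd) {
  if (sd <= 0) return(arr)
  half <- max(1L, ceiling(3 * sd))
  k <- exp(-((-half:half)^2) / (2 * sd^2))
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], half), v, rep(v[n], half))
    as.vector(stats::filter(vp, k, sides = 2))[(half + 1):(half + n)]
  }
  arr <- apply(arr, c(2, 3), conv1)                 # along axis 1
  arr <- aperm(apply(arr, c(1, 3), conv1), c(2, 1, 3))  # along axis 2
  arr <- aperm(apply(arr, c(1, 2), conv1), c(2, 3, 1))  # along axis 3
  arr
}

simulate_covariates <- function(n, cfg) {
  tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = runif(n, cfg$age_range[1], cfg$age_range[2]),
    sex = factor(sample(c("male", "female"), n, replace = TRUE),
                 levels = cohort_levels()$sex),
    smoking = factor(sample(c("never", "former", "current"), n, replace = TRUE,
                            prob = c(0.4, 0.3, 0.3)),
                     levels = cohort_levels()$smoking),
    education = factor(sample(c("<8", "8-10", ">10"), n, replace = TRUE,
                              prob = c(0.2, 0.5, 0.3)),
                       levels = cohort_levels()$education),
    physical_activity = factor(sample(c("none", "low", "moderate", "high"), n,
                                      replace = TRUE, prob = c(0.3, 0.3, 0.25, 0.15)),
                               levels = cohort_levels()$physical_activity),
    systolic_bp = rnorm(n, 130, 15),
    hba1c = rnorm(n, 5.5, 0.6),
    waist = rnorm(n, 90, 12),
    antihypertensive = rbinom(n, 1, 0.3),
    antidiabetic = rbinom(n, 1, 0.10),
    antidepressant = rbinom(n, 1, 0.10)
  )
}

simulate_genotypes <- function(n, panel) {
  g <- vapply(panel$frequency, function(f) rbinom(n, 2L, f), integer(n))
  colnames(g) <- panel$snp_id
  as_tibble(g)
}

# per-subject density-unit deficit inside the aging mask beyond the age trend
risk_deficit <- function(table, effects) {
  expo <- cbind(
    smoking_former = as.numeric(table$smoking == "former"),
    smoking_current = as.numeric(table$smoking == "current"),
    antihypertensive = as.numeric(table$antihypertensive),
    waist = table$waist - 90
  )
  as.vector(expo[, names(effects), drop = FALSE] %*% effects)
}

build_cohort <- function(cfg, table, genotypes, ad_status) {
  n <- nrow(table)
  p <- prod(cfg$grid)
  aging_idx <- which(cfg$aging_mask)
  ad_idx <- which(cfg$ad_mask)
  deficit <- cfg$aging_slope * (table$age - cfg$age_range[1]) +
    risk_deficit(table, cfg$risk_effects)
  expected <- matrix(cfg$baseline_gm, nrow = n, ncol = p,
                     dimnames = list(table$subject_id, NULL))
  expected[, aging_idx] <- expected[, aging_idx] - deficit
  if (any(ad_status)) {
    expected[ad_status, ad_idx] <- expected[ad_status, ad_idx] - cfg$ad_effect
  }
  values <- expected
  if (cfg$noise_sd > 0) {
    noise <- matrix(rnorm(n * p, sd = cfg$noise_sd), nrow = n)
    if (cfg$noise_smooth_sd > 0) {
      for (i in seq_len(n)) {
        noise[i, ] <- as.vector(smooth_gaussian_3d(array(noise[i, ], cfg$grid),
                                                   cfg$noise_smooth_sd))
      }
    }
    values <- values + noise
  }
  table <- dplyr::bind_cols(table, genotypes)
  table$ad_status <- ad_status
  # cognitive score declines with age and with total planted atrophy burden
  table$cognitive_score <- 30 - 0.05 * (table$age - cfg$age_range[1]) -
    0.15 * deficit - 1.5 * as.numeric(ad_status) + rnorm(n, sd = 1.5)
  maps <- map_set(values, grid = cfg$grid, subject_id = table$subject_id)
  truth <- list(aging_mask = cfg$aging_mask, ad_mask = cfg$ad_mask,
                expected = expected, deficit = deficit, config = cfg)
  structure(list(maps = maps, table = validate_cohort(table), truth = truth),
            class = "synthetic_cohort")
}

#' Generate a seeded synthetic cohort
#'
#' Draws ages uniformly over the configured range, simulates risk factors and
#' genotypes, plants the aging/risk/AD atrophy patterns described in
#' [generator_config()] and adds voxel noise. The returned `truth` record
#' (planted masks, per-subject deficit, noise-free expected maps) suffices to
#' reconstruct each subject's expected map exactly, so tests can score any
#' downstream stage against ground truth. Identical configurations (including
#' the seed) produce bit-identical cohorts.
#'
#' @param config a [generator_config()].
#' @return A `synthetic_cohort`: list with `maps` ([map_set()]), `table`
#'   (cohort tibble) and `truth`.
#' @examples
#' cohort <- generate_cohort(generator_config(n_subjects = 8, grid = c(6, 6, 6)))
#' cohort$maps
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  table <- simulate_covariates(config$n_subjects, config)
  genotypes <- simulate_genotypes(config$n_subjects, config$snp_panel)
  ad_status <- draw_ad_status(config, table, genotypes)
  build_cohort(config, table, genotypes, ad_status)
}

draw_ad_status <- function(cfg, table, genotypes) {
  n <- nrow(table)
  ad_status <- rep(FALSE, n)
  if (cfg$ad_fraction > 0) {
    old <- table$age >= cfg$ad_age_min
    if (any(old)) {
      pgs <- polygenic_score(genotypes, cfg$snp_panel)
      z <- if (sd(pgs) > 0) (pgs - mean(pgs)) / sd(pgs) else rep(0, n)
      pr <- plogis(qlogis(cfg$ad_fraction) + cfg$pgs_coupling * z)
      ad_status[old] <- runif(sum(old)) < pr[old]
    }
  }
  ad_status
}

#' Generate a reference AD-vs-control training set
#'
#' Emulates an external case-control training sample for an AD atrophy
#' classifier: all subjects are drawn from the upper tertile of the
#' configured age range, `n_ad` of them carry the planted AD deficit
#' (`ad_status = TRUE`) and `n_cn` are cognitively normal controls.
#' Everything else (risk factors, genotypes, noise) follows
#' [generate_cohort()].
#'
#' @param config a [generator_config()].
#' @param n_ad,n_cn group sizes (each at least 2).
#' @return A `synthetic_cohort` whose table carries `ad_status`.
#' @export
generate_reference_ad_set <- function(config, n_ad = 60, n_cn = 60) {
  stopifnot(inherits(config, "generator_config"))
  if (n_ad < 2 || n_cn < 2)
    abort("need at least 2 AD and 2 control subjects", class = "spareatlas_config_error")
  n <- n_ad + n_cn
  set.seed(config$seed)
  lo <- config$age_range[1] + 2 / 3 * diff(config$age_range)
  table <- simulate_covariates(n, config)
  table$age <- runif(n, lo, config$age_range[2])
  table$subject_id <- sprintf("REF%04d", seq_len(n))
  genotypes <- simulate_genotypes(n, config$snp_panel)
  ad_status <- rep(c(TRUE, FALSE), c(n_ad, n_cn))
  build_cohort(config, table, genotypes, ad_status)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %s grid, %d aging / %d AD mask voxels (%d shared)\n",
              n_maps(x$maps), paste(x$maps$grid, collapse = "x"),
              sum(x$truth$aging_mask), sum(x$truth$ad_mask),
              sum(x$truth$aging_mask & x$truth$ad_mask)))
  invisible(x)
}
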