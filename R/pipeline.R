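#' Configuration for the end-to-end analysis pipeline
#'
#' Bundles the generator settings and every stage threshold. The defaults
#' mirror the study design the package implements: training groups at
#' `age <= 45` vs `age >= 60`, aging groups defined among subjects `>= 65`
#' years by age-residual z-scores beyond +/-0.5, and voxel significance
#' masks at FDR `q <= 0.001`. The pipeline's default cohort plants the AD
#' deficit in an expected 15% of subjects aged 65+ (probability tilted by
#' the polygenic score), emulating preclinical AD prevalence in the elderly,
#' so that the AD-pattern contrast and the genetic association have signal.
#'
#' One master seed fans out to per-stage child seeds as
#' `seed * 8 + stage_offset` (offsets 1 = cohort, 2 = reference set,
#' 3 = jackknife folds), so stages can be rerun in isolation; the master
#' seed must stay below 2^27 to keep children in integer range.
#'
#' @param seed master integer seed.
#' @param generator a [generator_config()] (its seed is replaced by the
#'   cohort child seed); default plants `ad_fraction = 0.15`.
#' @param young_max,old_min training-group age bounds, years.
#' @param cost SVM regularization constant.
#' @param n_folds jackknife folds (`NULL` = automatic).
#' @param age_floor,z_threshold aging-group definition.
#' @param q_threshold FDR level for voxel masks.
#' @param n_ad,n_cn reference AD-vs-control set sizes.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, generator = NULL,
                       young_max = 45, old_min = 60, cost = 1, n_folds = NULL,
                       age_floor = 65, z_threshold = 0.5, q_threshold = 0.001,
                       n_ad = 60, n_cn = 60) {
  seed <- as.integer(seed)
  if (seed < 0 || seed >= 2^27) abort("seed must lie in [0, 2^27)", class = "spareatlas_config_error")
  generator <- generator %||% generator_config(ad_fraction = 0.15)
  structure(list(seed = seed, generator = generator, young_max = young_max,
                 old_min = old_min, cost = cost, n_folds = n_folds,
                 age_floor = age_floor, z_threshold = z_threshold,
                 q_threshold = q_threshold, n_ad = n_ad, n_cn = n_cn),
            class = "run_config")
}

child_seed <- function(seed, offset) as.integer(seed * 8L + offset)

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          class = "spareatlas_pipeline_error", parent = e)
  })
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulate -> train and jackknife-score the brain-aging index -> train the
#' AD index on a reference case-control set and score the cohort -> define
#' ABA/RA and high/low-AD groups -> voxel-wise contrasts with FDR masks ->
#' overlap partition and per-region densities -> polygenic score ->
#' association models. Deterministic given the config seed.
#'
#' When `out_dir` is given, every intermediate artifact is written in its
#' standard format (NIfTI masks, weight and statistic maps; CSV cohort and
#' coefficient tables; YAML config echo; JSON summary); artifacts of
#' completed stages persist even if a later stage fails. Per-subject maps
#' are only written with `keep_maps = TRUE` (they dominate disk use).
#'
#' @param config a [run_config()].
#' @param out_dir optional artifact directory.
#' @param keep_maps also write the per-subject simulated maps.
#' @return A `run_report` list: `summary` (plain list, JSON-serializable),
#'   `table` (augmented cohort tibble), `models`, `stat_maps`, `partition`,
#'   `fits` and `truth`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL, keep_maps = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  save_mask <- function(mask, name) {
    if (!is.null(out_dir)) write_mask(mask, file.path(out_dir, paste0(name, ".nii.gz")))
  }
  save_map <- function(arr, name) {
    if (!is.null(out_dir)) RNifti::writeNifti(arr, file.path(out_dir, paste0(name, ".nii.gz")),
                                              datatype = "float")
  }

  cfg_gen <- config$generator
  cfg_gen$seed <- child_seed(config$seed, 1L)
  cohort <- run_stage("simulate", generate_cohort(cfg_gen))
  cfg_ref <- cfg_gen
  cfg_ref$seed <- child_seed(config$seed, 2L)
  reference <- run_stage("reference", generate_reference_ad_set(cfg_ref, config$n_ad, config$n_cn))
  tab <- cohort$table
  if (!is.null(out_dir)) {
    save_mask(cohort$truth$aging_mask, "planted_aging_mask")
    save_mask(cohort$truth$ad_mask, "planted_ad_mask")
    if (keep_maps) write_maps(cohort$maps, file.path(out_dir, "maps"))
  }

  groups <- run_stage("train_groups",
                      select_training_groups(tab, config$young_max, config$old_min))
  ba <- run_stage("spare_ba", add_spare_scores(
    tab, cohort$maps,
    training = list(young = groups$young_ids, old = groups$old_ids),
    col = "spare_ba", cost = config$cost, n_folds = config$n_folds,
    seed = child_seed(config$seed, 3L)))
  tab <- ba$table
  model_ba <- ba$model

  model_ad <- run_stage("spare_ad", train_spare_classifier(
    reference$maps,
    ifelse(reference$table$ad_status, "ad", "cn"),
    positive_label = "ad", cost = config$cost))
  tab$spare_ad <- unname(score_subjects(model_ad, cohort$maps)[tab$subject_id])
  if (!is.null(out_dir)) {
    save_map(weight_map(model_ba), "weights_spare_ba")
    save_map(weight_map(model_ad), "weights_spare_ad")
  }

  tab <- run_stage("grouping", {
    tab <- label_aging_groups(tab, "spare_ba", config$age_floor, config$z_threshold)
    label_aging_groups(tab, "spare_ad", config$age_floor, config$z_threshold,
                       label_low = "LOW_AD", label_high = "HIGH_AD",
                       z_col = "z_residual_ad", label_col = "ad_group_label")
  })

  aba_ids <- tab$subject_id[which(tab$group_label == "ABA")]
  ra_ids <- tab$subject_id[which(tab$group_label == "RA")]
  high_ids <- tab$subject_id[which(tab$ad_group_label == "HIGH_AD")]
  low_ids <- tab$subject_id[which(tab$ad_group_label == "LOW_AD")]

  vox_a <- run_stage("voxstats_aba_ra",
                     voxelwise_ttest(cohort$maps[ra_ids], cohort$maps[aba_ids],
                                     q_threshold = config$q_threshold))
  vox_b <- run_stage("voxstats_ad",
                     voxelwise_ttest(cohort$maps[low_ids], cohort$maps[high_ids],
                                     q_threshold = config$q_threshold))
  part <- run_stage("overlap", overlap_partition(vox_a$mask, vox_b$mask))
  if (!is.null(out_dir)) {
    save_map(vox_a$t, "t_aba_vs_ra"); save_mask(vox_a$mask, "mask_aba_vs_ra")
    save_map(vox_b$t, "t_high_vs_low_ad"); save_mask(vox_b$mask, "mask_high_vs_low_ad")
    save_mask(part$a_only, "overlap_blue"); save_mask(part$b_only, "overlap_red")
    save_mask(part$both, "overlap_green")
    readr::write_csv(part$counts, file.path(out_dir, "overlap_counts.csv"), progress = FALSE)
  }

  region_tests <- run_stage("region_density", {
    purrr::imap(list(blue = part$a_only, red = part$b_only, green = part$both),
                function(mask, name) {
                  if (!any(mask)) return(NULL)
                  dens <- region_density(cohort$maps, mask)
                  dplyr::bind_cols(
                    tibble(region = name),
                    group_mean_test(dens$density[dens$subject_id %in% ra_ids],
                                    dens$density[dens$subject_id %in% aba_ids]))
                }) |> dplyr::bind_rows()
  })

  tab <- run_stage("pgs", add_polygenic_score(tab, cfg_gen$snp_panel))
  old <- tab$age >= config$age_floor
  fits <- run_stage("associations", fit_index_model(tab, "spare_ba"))
  assoc <- run_stage("index_associations", list(
    r_spareba_age = pearson_with_p(tab$spare_ba, tab$age),
    r_spareba_sparead = pearson_with_p(tab$spare_ba, tab$spare_ad),
    r_spareba_sparead_old = pearson_with_p(tab$spare_ba[old], tab$spare_ad[old]),
    aba_ra_sparead = group_mean_test(tab$spare_ad[tab$subject_id %in% aba_ids],
                                     tab$spare_ad[tab$subject_id %in% ra_ids]),
    pgs_spareba = outcome_adjusted_association(tab, "spare_ba", "pgs", c("age", "sex")),
    pgs_sparead = outcome_adjusted_association(tab, "spare_ad", "pgs", c("age", "sex")),
    pgs_sparead_old = outcome_adjusted_association(tab[old, ], "spare_ad", "pgs",
                                                   c("age", "sex")),
    cognitive_spareba = outcome_adjusted_association(tab, "cognitive_score", "spare_ba",
                                                     c("age", "sex", "education"))
  ))

  summary <- list(
    schema_version = 1L,
    seed = config$seed,
    n_subjects = nrow(tab),
    n_young = length(groups$young_ids), n_old = length(groups$old_ids),
    n_aba = length(aba_ids), n_ra = length(ra_ids),
    n_high_ad = length(high_ids), n_low_ad = length(low_ids),
    r_spareba_age = assoc$r_spareba_age$r,
    r_spareba_sparead = assoc$r_spareba_sparead$r,
    r_spareba_sparead_old = assoc$r_spareba_sparead_old$r,
    aba_mean_sparead = assoc$aba_ra_sparead$mean_a,
    ra_mean_sparead = assoc$aba_ra_sparead$mean_b,
    aba_ra_sparead_p = assoc$aba_ra_sparead$p,
    n_sig_aba_ra = sum(vox_a$mask), n_sig_high_low_ad = sum(vox_b$mask),
    overlap_counts = setNames(as.list(part$counts$n_voxels), part$counts$region),
    dice_fdr_vs_planted_aging = dice_coefficient(vox_a$mask, cohort$truth$aging_mask),
    dice_weightmask_vs_planted_aging = dice_coefficient(
      weight_mask(model_ba, sum(cohort$truth$aging_mask)), cohort$truth$aging_mask),
    pgs_spareba_p = assoc$pgs_spareba$p_value,
    pgs_sparead_p = assoc$pgs_sparead$p_value,
    pgs_sparead_old_p = assoc$pgs_sparead_old$p_value,
    region_shift = if (nrow(region_tests)) {
      setNames(as.list(region_tests$p), region_tests$region)
    } else list(),
    model_r_squared = setNames(as.list(glance(fits)$r_squared), glance(fits)$stratum)
  )

  if (!is.null(out_dir)) {
    write_cohort(tab, file.path(out_dir, "cohort.csv"))
    readr::write_csv(tidy(fits), file.path(out_dir, "risk_factor_model.csv"), progress = FALSE)
    if (nrow(region_tests))
      readr::write_csv(region_tests, file.path(out_dir, "region_shift_tests.csv"),
                       progress = FALSE)
    echo <- config
    echo$generator <- c(
      cfg_gen[setdiff(names(cfg_gen), c("aging_mask", "ad_mask", "snp_panel"))],
      list(n_aging_mask_voxels = sum(cfg_gen$aging_mask),
           n_ad_mask_voxels = sum(cfg_gen$ad_mask),
           n_snps = nrow(cfg_gen$snp_panel)))
    yaml::write_yaml(unclass_recursive(echo), file.path(out_dir, "config_echo.yaml"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(summary = summary, table = tab,
                 models = list(spare_ba = model_ba, spare_ad = model_ad),
                 stat_maps = list(aba_ra = vox_a, high_low_ad = vox_b),
                 partition = part, region_tests = region_tests, fits = fits,
                 truth = cohort$truth, config = config),
            class = "run_report")
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "<run_report> n=%d (young %d / old %d; ABA %d / RA %d)\n",
    "  r(SPARE-BA, age) = %.3f; r(SPARE-BA, SPARE-AD) = %.3f\n",
    "  SPARE-AD mean: ABA %.3f vs RA %.3f (p = %.2g)\n",
    "  significant voxels: aging contrast %d, AD contrast %d; overlap blue/red/green %d/%d/%d\n"),
    s$n_subjects, s$n_young, s$n_old, s$n_aba, s$n_ra,
    s$r_spareba_age, s$r_spareba_sparead,
    s$aba_mean_sparead, s$ra_mean_sparead, s$aba_ra_sparead_p,
    s$n_sig_aba_ra, s$n_sig_high_low_ad,
    s$overlap_counts$a_only, s$overlap_counts$b_only, s$overlap_counts$both))
  invisible(x)
}
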