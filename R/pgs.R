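#' Example 19-SNP Alzheimer risk panel
#'
#' A synthetic panel of 19 biallelic SNPs with risk-allele frequencies and
#' per-allele odds ratios of magnitudes typical for genome-wide significant
#' Alzheimer loci (one strong APOE-like locus, the rest modest). The values
#' are illustrative, not the published loci; the same panel is also shipped
#' as `inst/extdata/synthetic_ad_snp_panel.csv`.
#'
#' @return Tibble with columns `snp_id`, `risk_allele`, `frequency`,
#'   `odds_ratio`.
#' @export
default_snp_panel <- function() {
  tibble(
    snp_id = sprintf("snp_%02d", 1:19),
    risk_allele = rep(c("A", "C", "G", "T"), length.out = 19),
    frequency = round(seq(0.10, 0.48, length.out = 19), 3),
    odds_ratio = c(2.50, 1.22, 0.81, 1.17, 0.88, 1.15, 1.10, 0.92, 1.12,
                   1.08, 0.90, 1.18, 1.06, 0.93, 1.14, 1.09, 0.87, 1.11, 1.20)
  )
}

#' Read a SNP panel from CSV
#'
#' Expects columns `snp_id` and `odds_ratio`; `risk_allele` and `frequency`
#' are optional.
#'
#' @param path CSV file path.
#' @export
read_snp_panel <- function(path) {
  panel <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("snp_id", "odds_ratio") %in% names(panel)))
    abort("panel needs columns snp_id and odds_ratio", class = "spareatlas_validation_error")
  if (anyDuplicated(panel$snp_id)) abort("duplicated snp_id in panel", class = "spareatlas_validation_error")
  if (any(panel$odds_ratio <= 0)) abort("odds ratios must be positive", class = "spareatlas_validation_error")
  as_tibble(panel)
}

#' Polygenic risk score as a weighted allele sum
#'
#' For each subject, the score is the sum over panel SNPs of the risk-allele
#' count (0, 1 or 2) weighted by the logarithm of that SNP's odds ratio:
#' `score = sum_j count_j * log(OR_j)`. The natural logarithm is the default
#' (the convention for odds-ratio weights); a different base is available via
#' `log_base`. Higher scores mean higher genetic Alzheimer risk, and
#' increasing any risk-allele count with OR > 1 strictly increases the score.
#'
#' Subjects with any missing genotype get a missing score by default
#' (listwise, mirroring analyses restricted to fully genotyped participants);
#' `na_action = "impute"` substitutes the panel's expected allele count
#' `2 * frequency` for missing entries instead.
#'
#' @param genotypes data frame or matrix of allele counts, columns named by
#'   `panel$snp_id`.
#' @param panel SNP panel tibble (see [default_snp_panel()]); needs
#'   `frequency` when imputing.
#' @param log_base base of the logarithm used for the weights.
#' @param na_action `"na"` (default) or `"impute"`.
#' @return Numeric score per subject.
#' @examples
#' polygenic_score(data.frame(a = 1, b = 2),
#'                 tibble::tibble(snp_id = c("a", "b"), odds_ratio = c(2, 0.5)))
#' @export
polygenic_score <- function(genotypes, panel, log_base = exp(1),
                            na_action = c("na", "impute")) {
  na_action <- match.arg(na_action)
  if (nrow(panel) == 0) abort("empty SNP panel", class = "spareatlas_validation_error")
  miss <- setdiff(panel$snp_id, colnames(genotypes))
  if (length(miss))
    abort(paste("genotype columns missing for:", paste(miss, collapse = ", ")),
          class = "spareatlas_validation_error")
  g <- as.matrix(as.data.frame(genotypes)[, panel$snp_id, drop = FALSE])
  if (any(!is.na(g) & !g %in% c(0, 1, 2)))
    abort("allele counts must be 0, 1, 2 or missing", class = "spareatlas_validation_error")
  if (na_action == "impute" && anyNA(g)) {
    if (!"frequency" %in% names(panel))
      abort("panel needs a frequency column to impute", class = "spareatlas_validation_error")
    for (j in seq_len(ncol(g))) g[is.na(g[, j]), j] <- 2 * panel$frequency[j]
  }
  w <- log(panel$odds_ratio, base = log_base)
  as.vector(g %*% w)
}

#' Add a polygenic risk score column to a cohort table
#'
#' Tidyverse-style verb: looks up the panel's genotype columns in `table` and
#' appends the score as `pgs`.
#'
#' @param table cohort tibble with `snp_*` allele-count columns.
#' @inheritParams polygenic_score
#' @return `table` with a `pgs` column.
#' @export
add_polygenic_score <- function(table, panel = default_snp_panel(),
                                log_base = exp(1), na_action = c("na", "impute")) {
  table$pgs <- polygenic_score(table, panel, log_base = log_base,
                               na_action = na_action)
  table
}
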