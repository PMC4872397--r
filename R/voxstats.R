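#' Voxel-wise two-group Student t-test
#'
#' Mass-univariate comparison of two groups of volumetric maps: a two-sided
#' pooled-variance (Student) t-test at every voxel of the analysis mask, with
#' `df = n1 + n2 - 2`, followed by Benjamini-Hochberg FDR adjustment across
#' mask voxels. Welch's unequal-variance test is available behind a flag.
#' Voxels with zero pooled variance are uninformative and get `t = 0, p = 1`
#' (counted in a message), never an exception.
#'
#' The default analysis mask keeps voxels with nonzero variance across the
#' pooled sample, which excludes empty background.
#'
#' @param maps_a,maps_b [map_set()]s (or matrices) for the two groups, on one
#'   grid. The t statistic is group A minus group B.
#' @param analysis_mask logical array (or `NULL` for the nonzero-variance
#'   default).
#' @param q_threshold FDR level defining the significance mask (default
#'   0.001).
#' @param welch use Welch's t instead of the pooled-variance Student t.
#' @return A `voxel_stat_map`: per-voxel `t`, `p`, `q` arrays, the logical
#'   significance `mask` (`q <= q_threshold`), the `analysis_mask`, `df`,
#'   `n1`, `n2`.
#' @export
voxelwise_ttest <- function(maps_a, maps_b, analysis_mask = NULL,
                            q_threshold = 0.001, welch = FALSE) {
  A <- as_values_matrix(maps_a)
  B <- as_values_matrix(maps_b)
  if (ncol(A) != ncol(B)) abort("groups are not on one grid", class = "spareatlas_shape_error")
  grid <- if (inherits(maps_a, "map_set")) maps_a$grid else NULL
  n1 <- nrow(A); n2 <- nrow(B)
  if (n1 < 2 || n2 < 2) abort("each group needs at least 2 subjects", class = "spareatlas_validation_error")
  p_vox <- ncol(A)
  m1 <- colMeans(A); m2 <- colMeans(B)
  v1 <- colSums(sweep(A, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(B, 2, m2)^2) / (n2 - 1)
  if (is.null(analysis_mask)) {
    tot_var <- v1 * (n1 - 1) + v2 * (n2 - 1) + n1 * n2 / (n1 + n2) * (m1 - m2)^2
    analysis_mask <- tot_var > 0
  } else {
    if (!is.null(grid)) analysis_mask <- resolve_mask(analysis_mask, grid)
    analysis_mask <- as.vector(analysis_mask)
  }
  tstat <- rep(NA_real_, p_vox); pval <- rep(NA_real_, p_vox)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df_w <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
    tt <- (m1 - m2) / sqrt(se2)
    df_used <- df_w
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df_used <- rep(n1 + n2 - 2, p_vox)
  }
  degen <- analysis_mask & !is.finite(tt)
  if (any(degen)) inform(sprintf("%d constant voxel(s) set to p = 1", sum(degen)))
  tt[degen] <- 0
  df_used[degen & !is.finite(df_used)] <- n1 + n2 - 2
  inside <- which(analysis_mask)
  tstat[inside] <- tt[inside]
  pval[inside] <- 2 * pt(abs(tt[inside]), df = df_used[inside], lower.tail = FALSE)
  fdr <- fdr_bh(pval[inside], q_threshold)
  qval <- rep(NA_real_, p_vox); qval[inside] <- fdr$q
  sig <- rep(FALSE, p_vox); sig[inside] <- fdr$mask
  shape <- function(x) if (!is.null(grid)) array(x, dim = grid) else x
  structure(list(t = shape(tstat), p = shape(pval), q = shape(qval),
                 mask = shape(sig), analysis_mask = shape(analysis_mask),
                 df = if (welch) NA_real_ else n1 + n2 - 2,
                 n1 = n1, n2 = n2, grid = grid,
                 q_threshold = q_threshold, kind = "two-group t"),
            class = "voxel_stat_map")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone-enforced) over the supplied voxels,
#' plus the significance mask `q <= q_threshold`. NA entries pass through as
#' NA and are not counted in the number of tests.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q_threshold FDR level.
#' @return List with `q` and logical `mask`.
#' @export
fdr_bh <- function(p_values, q_threshold = 0.05) {
  if (length(p_values) == 0) return(list(q = numeric(0), mask = logical(0)))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    abort("p-values must lie in [0, 1]", class = "spareatlas_validation_error")
  q <- p.adjust(p_values, method = "BH")
  list(q = q, mask = !is.na(q) & q <= q_threshold)
}

#' Voxel-wise association map for a continuous covariate
#'
#' Per-voxel OLS of density on a continuous covariate (plus optional
#' adjuster columns), with the t statistic of the covariate coefficient and
#' the same FDR machinery as [voxelwise_ttest()]. Used, e.g., to map atrophy
#' against a continuous age-adjusted index instead of a dichotomized group
#' contrast.
#'
#' @param maps [map_set()] or matrix.
#' @param covariate numeric vector, one value per map.
#' @param adjusters optional numeric matrix/data frame of nuisance covariates.
#' @inheritParams voxelwise_ttest
#' @return A `voxel_stat_map` with the covariate's t, p, q and mask.
#' @export
continuous_association_map <- function(maps, covariate, adjusters = NULL,
                                       analysis_mask = NULL, q_threshold = 0.001) {
  Y <- as_values_matrix(maps)
  grid <- if (inherits(maps, "map_set")) maps$grid else NULL
  if (length(covariate) != nrow(Y)) abort("one covariate value per map", class = "spareatlas_validation_error")
  if (var(covariate) == 0) abort("covariate has zero variance", class = "spareatlas_validation_error")
  X <- cbind(`(intercept)` = 1, covariate = covariate)
  if (!is.null(adjusters)) {
    adjusters <- as.matrix(adjusters)
    colnames(adjusters) <- colnames(adjusters) %||% paste0("adj", seq_len(ncol(adjusters)))
    X <- cbind(X, adjusters)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste("rank-deficient design; collinear column(s):",
                paste(aliased, collapse = ", ")),
          class = "spareatlas_validation_error")
  }
  n <- nrow(Y); k <- ncol(X); dfree <- n - k
  if (dfree < 1) abort("not enough subjects for the design", class = "spareatlas_validation_error")
  XtXinv <- solve(crossprod(X))
  Beta <- XtXinv %*% t(X) %*% Y            # k x voxels
  resid <- Y - X %*% Beta
  sigma2 <- colSums(resid^2) / dfree
  se <- sqrt(sigma2 * XtXinv[2, 2])
  tt <- Beta[2, ] / se
  if (is.null(analysis_mask)) {
    analysis_mask <- apply(Y, 2, var) > 0
  } else {
    if (!is.null(grid)) analysis_mask <- resolve_mask(analysis_mask, grid)
    analysis_mask <- as.vector(analysis_mask)
  }
  degen <- analysis_mask & !is.finite(tt)
  if (any(degen)) inform(sprintf("%d degenerate voxel(s) set to p = 1", sum(degen)))
  tt[degen] <- 0
  p_vox <- ncol(Y)
  tstat <- rep(NA_real_, p_vox); pval <- rep(NA_real_, p_vox)
  inside <- which(analysis_mask)
  tstat[inside] <- tt[inside]
  pval[inside] <- 2 * pt(abs(tt[inside]), df = dfree, lower.tail = FALSE)
  fdr <- fdr_bh(pval[inside], q_threshold)
  qval <- rep(NA_real_, p_vox); qval[inside] <- fdr$q
  sig <- rep(FALSE, p_vox); sig[inside] <- fdr$mask
  shape <- function(x) if (!is.null(grid)) array(x, dim = grid) else x
  structure(list(t = shape(tstat), p = shape(pval), q = shape(qval),
                 mask = shape(sig), analysis_mask = shape(analysis_mask),
                 df = dfree, n1 = n, n2 = NA_integer_, grid = grid,
                 q_threshold = q_threshold, kind = "continuous association"),
            class = "voxel_stat_map")
}

#' @export
print.voxel_stat_map <- function(x, ...) {
  cat(sprintf("<voxel_stat_map> %s: %d analysis voxels, %d significant at q<=%g (df=%s)\n",
              x$kind, sum(x$analysis_mask), sum(x$mask), x$q_threshold,
              format(x$df)))
  invisible(x)
}

#' Tidy a voxel statistic map
#'
#' One row per analysis-mask voxel with 0-based voxel coordinates, t, p, q
#' and the significance flag.
#'
#' @param x a `voxel_stat_map`.
#' @param ... unused.
#' @export
tidy.voxel_stat_map <- function(x, ...) {
  idx <- which(as.vector(x$analysis_mask))
  coords <- if (!is.null(x$grid)) arrayInd(idx, x$grid) - 1L else cbind(idx - 1L, NA, NA)
  tibble(x_vox = coords[, 1], y_vox = coords[, 2], z_vox = coords[, 3],
         t = as.vector(x$t)[idx], p = as.vector(x$p)[idx],
         q = as.vector(x$q)[idx], significant = as.vector(x$mask)[idx])
}

#' @export
glance.voxel_stat_map <- function(x, ...) {
  tibble(kind = x$kind, n_analysis = sum(x$analysis_mask),
         n_significant = sum(x$mask), q_threshold = x$q_threshold,
         df = x$df, n1 = x$n1, n2 = x$n2)
}

#' Partition two significance masks into exclusive and shared regions
#'
#' Given the aging-contrast mask A and the AD-contrast mask B, returns the
#' three disjoint voxel sets `a_only` ("blue": aging-specific), `b_only`
#' ("red": AD-specific) and `both` ("green": shared), with
#' `a_only | both = A` and `b_only | both = B`.
#'
#' @param mask_a,mask_b logical arrays on one grid.
#' @return An `overlap_partition` with the three masks and a `counts` tibble.
#' @export
overlap_partition <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    abort("masks are not on one grid", class = "spareatlas_shape_error")
  a_only <- mask_a & !mask_b
  b_only <- mask_b & !mask_a
  both <- mask_a & mask_b
  structure(list(a_only = a_only, b_only = b_only, both = both,
                 counts = tibble(region = c("a_only", "b_only", "both"),
                                 n_voxels = c(sum(a_only), sum(b_only), sum(both)))),
            class = "overlap_partition")
}

#' @export
print.overlap_partition <- function(x, ...) {
  cat("<overlap_partition>\n")
  print(x$counts)
  invisible(x)
}

#' Per-subject mean density within a voxel region
#'
#' Arithmetic mean of each subject's map over the region — the per-region
#' gray-matter volume summaries whose distributions are compared between
#' groups (a shift indicates volume reduction in that region).
#'
#' @param maps a [map_set()] or matrix.
#' @param voxel_set logical array, `mask_spec`, or voxel index vector;
#'   must be non-empty.
#' @return Tibble with `subject_id` and `density`.
#' @export
region_density <- function(maps, voxel_set) {
  X <- as_values_matrix(maps)
  if (is.array(voxel_set) || inherits(voxel_set, "mask_spec")) {
    grid <- if (inherits(maps, "map_set")) maps$grid else dim(voxel_set)
    voxel_set <- which(resolve_mask(voxel_set, grid))
  }
  if (length(voxel_set) == 0) abort("empty voxel set", class = "spareatlas_validation_error")
  tibble(subject_id = rownames(X) %||% as.character(seq_len(nrow(X))),
         density = unname(rowMeans(X[, voxel_set, drop = FALSE])))
}
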