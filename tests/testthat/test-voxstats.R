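mat_maps <- function(values, grid) {
  map_set(values, grid = grid)
}

test_that("pooled t matches the hand-computed fixture and scalar t.test", {
  # one voxel: (1,2,3) vs (4,5,6)
  a <- matrix(c(1, 2, 3), ncol = 1)
  b <- matrix(c(4, 5, 6), ncol = 1)
  vs <- voxelwise_ttest(a, b, q_threshold = 0.05)
  expect_equal(vs$t[1], -3.674235, tolerance = 1e-6)
  expect_equal(vs$df, 4)
  expect_equal(vs$p[1], 0.02131164, tolerance = 1e-6)
  # random fixture: every voxel matches t.test / the brute-force oracle
  set.seed(5)
  A <- matrix(rnorm(8 * 50), 8)
  B <- matrix(rnorm(6 * 50, mean = 0.3), 6)
  vs2 <- voxelwise_ttest(A, B, q_threshold = 0.05)
  for (v in c(1, 17, 50)) {
    ref <- t.test(A[, v], B[, v], var.equal = TRUE)
    orc <- oracle_pooled_t(A[, v], B[, v])
    expect_equal(vs2$t[v], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(vs2$p[v], ref$p.value, tolerance = 1e-10)
    expect_equal(vs2$t[v], orc$t, tolerance = 1e-10)
  }
  vsw <- voxelwise_ttest(A, B, q_threshold = 0.05, welch = TRUE)
  for (v in c(3, 33)) {
    ref <- t.test(A[, v], B[, v])
    expect_equal(vsw$t[v], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(vsw$p[v], ref$p.value, tolerance = 1e-10)
  }
})

test_that("identical groups give t = 0, p = 1; constant voxels never throw", {
  A <- matrix(rnorm(12), 4)
  vs <- voxelwise_ttest(A, A, q_threshold = 0.05)
  expect_true(all(vs$t == 0))
  expect_true(all(vs$p == 1))
  B <- cbind(A, 7)  # constant voxel joins via explicit analysis mask
  expect_message(
    vs2 <- voxelwise_ttest(B, B, analysis_mask = rep(TRUE, 4), q_threshold = 0.05),
    "constant")
  expect_equal(vs2$p[4], 1)
})

test_that("null voxel p-values are uniformly distributed", {
  set.seed(9)
  A <- matrix(rnorm(10 * 500), 10)
  B <- matrix(rnorm(10 * 500), 10)
  vs <- voxelwise_ttest(A, B, q_threshold = 0.05)
  frac <- mean(vs$p < 0.05)
  expect_lt(abs(frac - 0.05), 4 * sqrt(0.05 * 0.95 / 500))
  expect_gt(suppressWarnings(ks.test(vs$p, "punif")$p.value), 0.01)
})

test_that("BH adjustment matches the textbook example and the brute-force oracle", {
  out <- fdr_bh(c(0.001, 0.02, 0.03, 0.04), q_threshold = 0.05)
  expect_equal(out$q, c(0.004, 0.04, 0.04, 0.04), tolerance = 1e-12)
  expect_true(all(out$mask))
  expect_false(any(fdr_bh(rep(1, 10), 0.05)$mask))
  expect_identical(fdr_bh(numeric(0), 0.05), list(q = numeric(0), mask = logical(0)))
  expect_error(fdr_bh(c(0.5, 1.2), 0.05), class = "spareatlas_validation_error")
  set.seed(14)
  for (rep in 1:20) {
    m <- sample(c(1, 5, 100, 1000), 1)
    p <- round(runif(m), sample(c(1, 3, 8), 1))  # rounding induces ties
    expect_equal(fdr_bh(p, 0.05)$q, oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("BH controls the realized false discovery rate under the null", {
  set.seed(77)
  q <- 0.05
  fdp <- replicate(1000, {
    p <- runif(100)
    r <- sum(fdr_bh(p, q)$mask)
    if (r == 0) 0 else 1  # all rejections are false under the global null
  })
  # under the global null, E[FDP] = P(any rejection) <= q
  expect_lte(mean(fdp), q + 3 * sqrt(q * (1 - q) / 1000))
})

test_that("continuous association maps recover a planted per-subject scalar", {
  grid <- c(6, 6, 6)
  mask <- resolve_mask(mask_sphere(c(2.5, 2.5, 2.5), 2), grid)
  set.seed(3)
  scal <- runif(30, 0, 5)
  values <- matrix(100, 30, prod(grid))
  values[, which(mask)] <- 100 - outer(scal, rep(1, sum(mask)))
  vs <- continuous_association_map(mat_maps(values, grid), scal, q_threshold = 0.001)
  expect_identical(vs$mask, mask)  # exactly the planted voxels
  # permuted covariate: no real association survives
  vs0 <- continuous_association_map(mat_maps(values, grid), sample(scal),
                                    q_threshold = 0.001)
  expect_lte(sum(vs0$mask), 2)
  expect_error(
    continuous_association_map(mat_maps(values, grid), scal, adjusters = cbind(x = scal)),
    regexp = "collinear", class = "spareatlas_validation_error")
  expect_error(continuous_association_map(mat_maps(values, grid), rep(1, 30)),
               class = "spareatlas_validation_error")
})

test_that("continuous association t matches per-voxel lm", {
  set.seed(6)
  Y <- matrix(rnorm(25 * 30), 25)
  x <- rnorm(25)
  adj <- cbind(a1 = rnorm(25))
  vs <- continuous_association_map(Y, x, adjusters = adj, q_threshold = 0.05)
  for (v in c(2, 30)) {
    sm <- summary(lm(Y[, v] ~ x + adj))$coefficients
    expect_equal(vs$t[v], sm["x", 3], tolerance = 1e-8)
    expect_equal(vs$p[v], sm["x", 4], tolerance = 1e-8)
  }
})

test_that("overlap partition is an exact three-way set partition", {
  g <- c(5, 5, 5)
  A <- resolve_mask(mask_box(c(0, 0, 0), c(2, 4, 4)), g)
  expect_identical(overlap_partition(A, A)$counts$n_voxels, c(0L, 0L, sum(A)))
  B <- resolve_mask(mask_box(c(4, 0, 0), c(4, 4, 4)), g)
  expect_equal(overlap_partition(A, B)$counts$n_voxels[3], 0)
  set.seed(10)
  for (rep in 1:5) {
    ra <- array(runif(125) < 0.4, g)
    rb <- array(runif(125) < 0.4, g)
    part <- overlap_partition(ra, rb)
    # brute-force per-voxel boolean enumeration
    for (i in which(ra | rb)) {
      expect_identical(part$a_only[i], ra[i] && !rb[i])
      expect_identical(part$b_only[i], rb[i] && !ra[i])
      expect_identical(part$both[i], ra[i] && rb[i])
    }
    expect_identical(part$a_only | part$both, ra)
    expect_identical(part$b_only | part$both, rb)
    expect_false(any(part$a_only & part$b_only))
  }
  expect_error(overlap_partition(A, array(TRUE, c(4, 4, 4))),
               class = "spareatlas_shape_error")
})

test_that("region densities are per-subject means over the voxel set", {
  g <- c(4, 4, 4)
  values <- matrix(7, 3, 64)
  values[2, ] <- 1:64
  d <- region_density(mat_maps(values, g), rep(TRUE, 64) |> array(dim = g))
  expect_equal(d$density, c(7, mean(1:64), 7))
  d1 <- region_density(mat_maps(values, g), 5L)
  expect_equal(d1$density[2], 5)
  expect_error(region_density(mat_maps(values, g), integer(0)),
               class = "spareatlas_validation_error")
})
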