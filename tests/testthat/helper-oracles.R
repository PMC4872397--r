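# Independent brute-force oracles, deliberately naive implementations kept
# separate from the package code paths they check.

# Benjamini-Hochberg step-up by direct definition: q_(i) = min_{j >= i} p_(j) m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(ps[i:m] * m / (i:m), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# pooled-variance two-sample t by hand
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

# Pearson r and its t-based p by the textbook formulas
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(abs(t), n - 2, lower.tail = FALSE))
}

# OLS through explicit normal equations, with classical standard errors
oracle_ols <- function(X, y) {
  XtXinv <- solve(t(X) %*% X)
  beta <- XtXinv %*% t(X) %*% y
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(XtXinv) * sigma2)
  t <- as.vector(beta) / se
  list(beta = as.vector(beta), se = se,
       p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

# weighted allele sum by explicit double loop
oracle_pgs <- function(counts, odds_ratios) {
  out <- numeric(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    s <- 0
    for (j in seq_len(ncol(counts))) s <- s + counts[i, j] * log(odds_ratios[j])
    out[i] <- s
  }
  out
}

# small-grid generator configs used across test files
tiny_config <- function(n = 40, grid = c(8, 8, 8), seed = 1, ...) {
  a <- pmax(ceiling(grid * 0.55) - 1, 1)     # aging box corner
  b <- max(floor(grid[1] * 0.4), 1)          # AD box start (inside aging box)
  generator_config(n_subjects = n, grid = grid,
                   aging_mask = mask_box(c(0, 0, 0), a),
                   ad_mask = mask_box(c(b, 0, 0), c(grid[1] - 1, a[2], a[3])),
                   seed = seed, ...)
}
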