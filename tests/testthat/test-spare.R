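# small perfectly separable fixture: one informative voxel block
separable_maps <- function(n_per = 3, p = 20, gap = 2, seed = 4) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * p, sd = 0.05), nrow = 2 * n_per)
  X[seq_len(n_per), 1:4] <- X[seq_len(n_per), 1:4] + gap
  rownames(X) <- sprintf("s%02d", seq_len(2 * n_per))
  list(X = X, labels = rep(c("hi", "lo"), each = n_per))
}

test_that("training-group selection applies inclusive age bounds", {
  tab <- tibble::tibble(subject_id = letters[1:4], age = c(30, 45, 50, 60),
                        sex = "male")
  expect_error(select_training_groups(tab),  # old group of size 1
               class = "spareatlas_config_error")
  tab2 <- tibble::tibble(subject_id = letters[1:6],
                         age = c(30, 45, 50, 60, 61, 44), sex = "male")
  g <- select_training_groups(tab2)
  expect_setequal(g$young_ids, c("a", "b", "f"))  # 45 inclusive
  expect_setequal(g$old_ids, c("d", "e"))         # 60 inclusive
  expect_false("c" %in% unlist(g))                # middle excluded
  tab3 <- tibble::tibble(subject_id = letters[1:4], age = rep(50, 4), sex = "male")
  expect_error(select_training_groups(tab3), class = "spareatlas_config_error")
  expect_error(select_training_groups(tab2, young_max = 60, old_min = 45),
               class = "spareatlas_config_error")
})

test_that("uniform-age training group sizes match the closed form", {
  set.seed(8)
  tab <- tibble::tibble(subject_id = as.character(1:1000),
                        age = runif(1000, 20, 90))
  g <- select_training_groups(tab)
  p_young <- 25 / 70
  p_old <- 30 / 70
  expect_lt(abs(length(g$young_ids) - 1000 * p_young),
            4 * sqrt(1000 * p_young * (1 - p_young)))
  expect_lt(abs(length(g$old_ids) - 1000 * p_old),
            4 * sqrt(1000 * p_old * (1 - p_old)))
})

test_that("separable fixtures train to perfect, sign-consistent separation", {
  fx <- separable_maps()
  m <- train_spare_classifier(fx$X, fx$labels, positive_label = "hi")
  expect_true(all(m$training_scores[fx$labels == "hi"] > 0))
  expect_true(all(m$training_scores[fx$labels == "lo"] < 0))
  # label swap (positive class flipped) negates every score exactly
  m2 <- train_spare_classifier(fx$X, fx$labels, positive_label = "lo")
  expect_equal(m2$training_scores, -m$training_scores, tolerance = 1e-8)
  expect_equal(score_subjects(m2, fx$X), -score_subjects(m, fx$X), tolerance = 1e-8)
})

test_that("scoring training maps reproduces stored training decision values", {
  fx <- separable_maps(n_per = 4)
  m <- train_spare_classifier(fx$X, fx$labels)
  expect_equal(score_subjects(m, fx$X), m$training_scores, tolerance = 1e-10)
  expect_error(score_subjects(m, fx$X[, 1:10]), class = "spareatlas_shape_error")
})

test_that("the midpoint of a symmetric two-point training set scores zero", {
  X <- rbind(a1 = c(0, 1), a2 = c(0, 1), b1 = c(2, 3), b2 = c(2, 3))
  m <- train_spare_classifier(X, c("A", "A", "B", "B"), positive_label = "A")
  mid <- matrix(c(1, 2), nrow = 1)
  expect_equal(unname(score_subjects(m, mid)), 0, tolerance = 1e-8)
})

test_that("constant voxels are dropped with a message; all-constant errors", {
  X <- cbind(c(0, 0, 1, 1), 5, c(0.1, -0.1, 1.1, 0.9))
  expect_message(m <- train_spare_classifier(X, c("a", "a", "b", "b")),
                 "constant voxel")
  expect_equal(length(m$kept), 2)
  expect_error(train_spare_classifier(matrix(1, 4, 3), c("a", "a", "b", "b")),
               class = "spareatlas_validation_error")
})

test_that("noise-free planted cohorts concentrate SVM weight in the aging mask", {
  cfg <- tiny_config(n = 30, grid = c(10, 10, 10), noise_sd = 0, seed = 6,
                     risk_effects = c(smoking_former = 0, smoking_current = 0,
                                      antihypertensive = 0, waist = 0))
  co <- generate_cohort(cfg)
  g <- select_training_groups(co$table)
  lab <- rep(c("young", "old"), c(length(g$young_ids), length(g$old_ids)))
  m <- suppressMessages(
    train_spare_classifier(co$maps[c(g$young_ids, g$old_ids)], lab,
                           positive_label = "young"))
  w <- abs(as.vector(weight_map(m)))
  inside <- which(co$truth$aging_mask)
  expect_gte(sum(w[inside]) / sum(w), 0.9)
  wm <- weight_mask(m, sum(co$truth$aging_mask))
  expect_gte(dice_coefficient(wm, co$truth$aging_mask), 0.9)
})

test_that("leave-one-out jackknife scores are sign-correct on separable data", {
  fx <- separable_maps(n_per = 3)
  sc <- jackknife_scores(fx$X, fx$labels, positive_label = "hi", n_folds = 6)
  expect_true(all(sc[fx$labels == "hi"] > 0))
  expect_true(all(sc[fx$labels == "lo"] < 0))
  # fold bookkeeping: every subject held out exactly once
  expect_identical(sort(attr(sc, "fold")), 1:6)
})

test_that("a duplicated subject's held-out score matches its twin's full-model score", {
  fx <- separable_maps(n_per = 3)
  X <- rbind(fx$X, dup = fx$X[1, ])
  labels <- c(fx$labels, fx$labels[1])
  sc <- jackknife_scores(X, labels, positive_label = "hi", n_folds = nrow(X))
  full <- train_spare_classifier(X, labels, positive_label = "hi")
  expect_lt(abs(sc["dup"] - full$training_scores["s01"]), 1e-3)
})

test_that("jackknife fold partition is seeded, stratified and validated", {
  fx <- separable_maps(n_per = 6)
  s1 <- jackknife_scores(fx$X, fx$labels, positive_label = "hi", n_folds = 3, seed = 1)
  s2 <- jackknife_scores(fx$X, fx$labels, positive_label = "hi", n_folds = 3, seed = 1)
  expect_identical(s1, s2)
  # separable noise-free case: held-out signs invariant to the fold seed
  s3 <- jackknife_scores(fx$X, fx$labels, positive_label = "hi", n_folds = 3, seed = 2)
  expect_identical(as.vector(sign(s1)), as.vector(sign(s3)))
  for (s in c(1, 2)) {
    f <- attr(jackknife_scores(fx$X, fx$labels, n_folds = 3, seed = s), "fold")
    expect_true(all(table(f, fx$labels) == 2))  # stratification
  }
  expect_error(jackknife_scores(fx$X, fx$labels, n_folds = 8),
               class = "spareatlas_config_error")
})

test_that("permuted labels give jackknife scores with no group separation", {
  set.seed(21)
  X <- matrix(rnorm(24 * 40), nrow = 24)
  rownames(X) <- sprintf("r%02d", 1:24)
  labels <- sample(rep(c("a", "b"), 12))
  sc <- jackknife_scores(X, labels, positive_label = "a", n_folds = 4, seed = 3)
  d <- mean(sc[labels == "a"]) - mean(sc[labels == "b"])
  se <- sqrt(var(sc[labels == "a"]) / 12 + var(sc[labels == "b"]) / 12)
  expect_lt(abs(d), 4 * se)
})

test_that("add_spare_scores jackknifes training members and scores the rest", {
  cfg <- tiny_config(n = 40, grid = c(8, 8, 8), seed = 10)
  co <- generate_cohort(cfg)
  g <- select_training_groups(co$table)
  res <- suppressMessages(add_spare_scores(
    co$table, co$maps, list(young = g$young_ids, old = g$old_ids)))
  expect_true(all(is.finite(res$table$spare_ba)))
  # non-training members are scored by the full model
  full <- score_subjects(res$model, co$maps)
  ids_rest <- setdiff(co$table$subject_id, c(g$young_ids, g$old_ids))
  got <- setNames(res$table$spare_ba, res$table$subject_id)
  expect_equal(got[ids_rest], full[ids_rest], tolerance = 1e-10)
})
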