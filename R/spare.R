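#' Select young and old training groups by age thresholds
#'
#' The brain-aging index is trained to separate a relatively young group
#' (`age <= young_max`) from a relatively old group (`age >= old_min`);
#' subjects with intermediate ages are excluded from training and scored by
#' the fitted model only. Both bounds are inclusive.
#'
#' @param table cohort tibble with `subject_id` and `age`.
#' @param young_max upper age bound of the young group, years (default 45).
#' @param old_min lower age bound of the old group, years (default 60).
#' @return List with `young_ids` and `old_ids`.
#' @export
select_training_groups <- function(table, young_max = 45, old_min = 60) {
  if (young_max >= old_min) abort("young_max must be below old_min", class = "spareatlas_config_error")
  young <- table$subject_id[!is.na(table$age) & table$age <= young_max]
  old <- table$subject_id[!is.na(table$age) & table$age >= old_min]
  if (length(young) < 2 || length(old) < 2)
    abort("each training group needs at least 2 subjects", class = "spareatlas_config_error")
  list(young_ids = young, old_ids = old)
}

#' Train a SPARE-style linear SVM classifier on volumetric maps
#'
#' Fits a linear support-vector machine on flattened voxel features after
#' per-voxel z-standardization with training-set statistics. The decision
#' value `d(x) = <w, x_std> + b` is the SPARE index: the sign convention is
#' fixed so that subjects of `positive_label` score positive on average. For
#' a brain-aging index train young-vs-old with the young group positive
#' (higher score = less aging atrophy); for an AD index train AD-vs-control
#' with the AD group positive (higher score = more AD-like atrophy).
#'
#' Voxels that are constant across the training set carry no information and
#' are dropped (with a message); scoring re-applies the stored center/scale so
#' training subjects reproduce their training-time decision values exactly.
#'
#' @param maps a [map_set()] (or subjects-by-voxels matrix) of the training
#'   subjects.
#' @param labels factor or character vector with exactly two levels, aligned
#'   with the rows of `maps`.
#' @param positive_label which label scores positive (defaults to the first
#'   level).
#' @param cost SVM regularization constant C (default 1).
#' @return An object of class `spare_model`.
#' @export
train_spare_classifier <- function(maps, labels, positive_label = NULL, cost = 1) {
  X <- as_values_matrix(maps)
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) != 2) abort("labels must have exactly two levels", class = "spareatlas_validation_error")
  if (length(labels) != nrow(X)) abort("one label per map", class = "spareatlas_validation_error")
  if (min(table(labels)) < 2) abort("each class needs at least 2 subjects", class = "spareatlas_validation_error")
  positive_label <- positive_label %||% levels(labels)[1]
  if (!positive_label %in% levels(labels)) abort("positive_label not among labels", class = "spareatlas_validation_error")
  negative_label <- setdiff(levels(labels), positive_label)

  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  kept <- which(scale > 0)
  if (length(kept) == 0) abort("all voxels constant across the training set", class = "spareatlas_validation_error")
  if (length(kept) < ncol(X))
    inform(sprintf("dropping %d constant voxel(s) from training", ncol(X) - length(kept)))
  Xs <- sweep(sweep(X[, kept, drop = FALSE], 2, center[kept]), 2, scale[kept], "/")

  fit <- e1071::svm(Xs, labels, kernel = "linear", cost = cost, scale = FALSE)
  w <- as.vector(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  scores <- as.vector(Xs %*% w) + b
  # enforce the sign convention empirically (e1071's internal sign depends on
  # factor level order)
  if (mean(scores[labels == positive_label]) < mean(scores[labels == negative_label])) {
    w <- -w
    b <- -b
    scores <- -scores
  }
  ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  structure(list(
    weights = w, offset = b, kept = kept, n_voxels = ncol(X),
    center = center[kept], scale = scale[kept],
    grid = if (inherits(maps, "map_set")) maps$grid else NULL,
    positive_label = positive_label, negative_label = negative_label,
    cost = cost, training_ids = ids,
    training_scores = setNames(scores, ids),
    n_sv = nrow(fit$SV)
  ), class = "spare_model")
}

#' @export
print.spare_model <- function(x, ...) {
  cat(sprintf("<spare_model> linear SVM %s(+) vs %s(-), C=%g, %d training subjects, %d SVs\n",
              x$positive_label, x$negative_label, x$cost,
              length(x$training_ids), x$n_sv))
  invisible(x)
}

#' Voxel weight map of a trained SPARE model
#'
#' Returns the SVM weight vector mapped back onto the full voxel grid
#' (dropped constant voxels get weight 0), as a 3D array when the model knows
#' its grid.
#'
#' @param model a `spare_model`.
#' @export
weight_map <- function(model) {
  w <- numeric(model$n_voxels)
  w[model$kept] <- model$weights
  if (!is.null(model$grid)) array(w, dim = model$grid) else w
}

#' Threshold a weight map into a pattern mask
#'
#' The `n_voxels` voxels of largest absolute weight, as a logical mask — used
#' to compare the learned atrophy pattern against a planted or anatomical
#' region of matching size.
#'
#' @param model a `spare_model`.
#' @param n_voxels mask size.
#' @export
weight_mask <- function(model, n_voxels) {
  w <- weight_map(model)
  idx <- order(abs(as.vector(w)), decreasing = TRUE)[seq_len(n_voxels)]
  m <- array(FALSE, dim = if (is.array(w)) dim(w) else length(w))
  m[idx] <- TRUE
  m
}

#' Score subjects with a trained SPARE model
#'
#' Applies the stored standardization and weight vector; scoring a training
#' subject reproduces its training-time decision value exactly.
#'
#' @param model a `spare_model`.
#' @param maps a [map_set()] or matrix on the model's grid.
#' @return Named numeric vector of decision-value scores.
#' @export
score_subjects <- function(model, maps) {
  X <- as_values_matrix(maps)
  if (ncol(X) != model$n_voxels)
    abort("maps are not on the model grid", class = "spareatlas_shape_error")
  Xs <- sweep(sweep(X[, model$kept, drop = FALSE], 2, model$center), 2, model$scale, "/")
  scores <- as.vector(Xs %*% model$weights) + model$offset
  setNames(scores, rownames(X))
}

#' Jackknife (cross-validated) SPARE scores for training members
#'
#' Training subjects must not be scored by a model that saw them. This
#' routine partitions the training set into label-stratified folds, refits
#' the classifier with each fold held out, and scores every subject with the
#' model from which it was excluded — uncontaminated generalization scores
#' for all training members. The default is true leave-one-out up to 200
#' training subjects and 10 folds above that.
#'
#' @inheritParams train_spare_classifier
#' @param n_folds number of folds; `NULL` picks the default. Must not exceed
#'   the smaller class.
#' @param seed integer seed for the fold partition (ignored for leave-one-out,
#'   which has no randomness).
#' @return Named numeric vector of held-out scores, in input order, with the
#'   fold assignment attached as attribute `"fold"`.
#' @export
jackknife_scores <- function(maps, labels, positive_label = NULL, cost = 1,
                             n_folds = NULL, seed = 1L) {
  X <- as_values_matrix(maps)
  labels <- as.factor(as.character(labels))
  n <- nrow(X)
  n_folds <- n_folds %||% if (n <= 200) n else 10L
  if (n_folds > min(table(labels)) && n_folds < n)
    abort("fold count exceeds the smallest class", class = "spareatlas_config_error")
  if (n_folds > n) abort("more folds than subjects", class = "spareatlas_config_error")

  fold <- integer(n)
  if (n_folds == n) {
    fold <- seq_len(n)
  } else {
    # stratified: spread each label's subjects over folds in seeded random order
    rng <- local({ set.seed(seed); lapply(split(seq_len(n), labels), sample) })
    for (idx in rng) fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  for (k in seq_len(n_folds)) {
    hold <- fold == k
    if (min(table(labels[!hold])) < 2)
      abort("a fold leaves fewer than 2 subjects in a class", class = "spareatlas_config_error")
  }
  scores <- numeric(n)
  for (k in seq_len(n_folds)) {
    hold <- which(fold == k)
    m <- train_spare_classifier(X[-hold, , drop = FALSE], labels[-hold],
                                positive_label = positive_label, cost = cost)
    scores[hold] <- score_subjects(m, X[hold, , drop = FALSE])
  }
  structure(setNames(scores, rownames(X)), fold = fold)
}

#' Add SPARE scores to a cohort table
#'
#' Trains a young-vs-old (or any two-group) SPARE model on the listed
#' training subjects, scores training members by jackknife and everyone else
#' by the full model, and appends the scores as a column. Returns both the
#' augmented table and the fitted model.
#'
#' @param table cohort tibble.
#' @param maps [map_set()] covering all table subjects.
#' @param training named list with two character vectors of subject ids; the
#'   first element is the positive class (e.g.
#'   `list(young = ..., old = ...)`).
#' @param col name of the score column to add.
#' @inheritParams jackknife_scores
#' @return List with `table` (augmented tibble) and `model` (`spare_model`).
#' @export
add_spare_scores <- function(table, maps, training, col = "spare_ba",
                             cost = 1, n_folds = NULL, seed = 1L) {
  stopifnot(length(training) == 2)
  ids <- unlist(training, use.names = FALSE)
  lab <- factor(rep(names(training), lengths(training)), levels = names(training))
  model <- train_spare_classifier(maps[ids], lab,
                                  positive_label = names(training)[1], cost = cost)
  jk <- jackknife_scores(maps[ids], lab, positive_label = names(training)[1],
                         cost = cost, n_folds = n_folds, seed = seed)
  rest <- setdiff(table$subject_id, ids)
  scores <- setNames(rep(NA_real_, nrow(table)), table$subject_id)
  scores[ids] <- jk
  if (length(rest)) scores[rest] <- score_subjects(model, maps[rest])
  table[[col]] <- as.vector(scores[table$subject_id])
  list(table = table, model = model)
}
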