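#' Volumetric map sets
#'
#' A `map_set` holds one gray-matter volumetric map per subject on a common
#' voxel grid, stored as a subjects-by-voxels matrix (voxels in array order)
#' together with the grid shape, subject identifiers and an affine orientation
#' matrix. RAVENS-style regional volumetric maps are the intended content, but
#' any scalar field on a common grid fits. All voxel values must be finite and
#' subject identifiers unique.
#'
#' @param values a numeric matrix (subjects x voxels), a list of 3D arrays, or
#'   a single 3D array (one subject).
#' @param grid integer vector of length 3; inferred from array input.
#' @param subject_id character vector of unique identifiers, one per subject.
#' @param affine optional 4x4 orientation matrix; defaults to identity (the
#'   analysis never uses world coordinates).
#' @return An object of class `map_set`.
#' @export
map_set <- function(values, grid = NULL, subject_id = NULL, affine = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    dims <- unique(lapply(values, dim))
    if (length(dims) != 1 || length(dims[[1]]) != 3)
      abort("all maps must be 3D arrays on one grid", class = "spareatlas_shape_error")
    grid <- as.integer(dims[[1]])
    if (is.null(subject_id)) subject_id <- names(values)
    values <- do.call(rbind, lapply(values, as.vector))
  } else if (is.array(values) && length(dim(values)) == 3) {
    grid <- as.integer(dim(values))
    values <- matrix(as.vector(values), nrow = 1)
  }
  values <- as.matrix(values)
  grid <- as.integer(grid)
  if (length(grid) != 3 || prod(grid) != ncol(values))
    abort("grid shape does not match the number of voxels", class = "spareatlas_shape_error")
  if (!all(is.finite(values)))
    abort("non-finite voxel values", class = "spareatlas_validation_error")
  if (is.null(subject_id)) subject_id <- sprintf("S%04d", seq_len(nrow(values)))
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id)) abort("subject ids must be unique", class = "spareatlas_validation_error")
  if (length(subject_id) != nrow(values)) abort("one subject id per map", class = "spareatlas_validation_error")
  rownames(values) <- subject_id
  if (is.null(affine)) affine <- diag(4)
  structure(list(values = values, grid = grid, subject_id = subject_id, affine = affine),
            class = "map_set")
}

#' @export
print.map_set <- function(x, ...) {
  cat(sprintf("<map_set> %d maps on a %s voxel grid (%d voxels)\n",
              nrow(x$values), paste(x$grid, collapse = "x"), ncol(x$values)))
  invisible(x)
}

#' @export
dim.map_set <- function(x) c(nrow(x$values), x$grid)

#' @export
as.matrix.map_set <- function(x, ...) x$values

#' Subset a map set by subject
#'
#' @param x a `map_set`.
#' @param i subject indices or identifiers.
#' @param ... unused.
#' @export
`[.map_set` <- function(x, i, ...) {
  map_set(x$values[i, , drop = FALSE], grid = x$grid,
          subject_id = x$subject_id[if (is.character(i)) match(i, x$subject_id) else i],
          affine = x$affine)
}

#' Number of maps in a map set
#' @param x a `map_set`.
#' @export
n_maps <- function(x) nrow(x$values)

#' Extract one subject's map as a 3D array
#' @param x a `map_set`.
#' @param subject subject index or identifier.
#' @export
map_array <- function(x, subject = 1L) {
  if (is.character(subject)) subject <- match(subject, x$subject_id)
  array(x$values[subject, ], dim = x$grid)
}

as_values_matrix <- function(maps) {
  if (inherits(maps, "map_set")) return(maps$values)
  if (is.matrix(maps)) return(maps)
  abort("expected a map_set or a subjects-by-voxels matrix", class = "spareatlas_validation_error")
}

check_same_grid <- function(maps, grid) {
  if (inherits(maps, "map_set") && !identical(maps$grid, as.integer(grid)))
    abort("map grid does not match", class = "spareatlas_shape_error")
  invisible(TRUE)
}
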