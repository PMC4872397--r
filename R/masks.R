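#' Geometric mask specifications
#'
#' Voxel masks used by the synthetic-data generator and the voxel statistics
#' are described as simple geometric primitives in 0-based voxel coordinates
#' and resolved to logical 3D arrays on a given grid. Axis-aligned boxes are
#' closed on both bounds; spheres include every voxel whose centre lies within
#' `radius` of `center`.
#'
#' @param lower,upper integer vectors of length 3, inclusive 0-based voxel
#'   bounds of the box.
#' @param center numeric vector of length 3, 0-based voxel coordinates.
#' @param radius sphere radius in voxels.
#' @return An object of class `mask_spec`.
#' @examples
#' resolve_mask(mask_box(c(0, 0, 0), c(1, 1, 1)), c(4, 4, 4))
#' @export
mask_box <- function(lower, upper) {
  stopifnot(length(lower) == 3, length(upper) == 3)
  if (any(upper < lower)) abort("box upper bound below lower bound", class = "spareatlas_config_error")
  structure(list(type = "box", lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "mask_spec")
}

#' @rdname mask_box
#' @export
mask_sphere <- function(center, radius) {
  stopifnot(length(center) == 3, radius > 0)
  structure(list(type = "sphere", center = as.numeric(center), radius = as.numeric(radius)),
            class = "mask_spec")
}

#' Resolve a mask specification to a logical array
#'
#' @param spec a `mask_spec`, or an already-resolved logical array (returned
#'   unchanged after a shape check).
#' @param grid integer vector of length 3.
#' @return Logical array of dimension `grid`.
#' @export
resolve_mask <- function(spec, grid) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3, all(grid > 0))
  if (is.array(spec)) {
    if (!identical(dim(spec), grid)) abort("mask shape does not match grid", class = "spareatlas_shape_error")
    return(array(as.logical(spec), dim = grid))
  }
  stopifnot(inherits(spec, "mask_spec"))
  # 0-based voxel coordinates, array order
  ix <- seq_len(grid[1]) - 1L
  iy <- seq_len(grid[2]) - 1L
  iz <- seq_len(grid[3]) - 1L
  if (spec$type == "box") {
    m <- outer(outer(ix >= spec$lower[1] & ix <= spec$upper[1],
                     iy >= spec$lower[2] & iy <= spec$upper[2], "&"),
               iz >= spec$lower[3] & iz <= spec$upper[3], "&")
  } else {
    dx2 <- (ix - spec$center[1])^2
    dy2 <- (iy - spec$center[2])^2
    dz2 <- (iz - spec$center[3])^2
    m <- outer(outer(dx2, dy2, "+"), dz2, "+") <= spec$radius^2
  }
  array(m, dim = grid)
}

#' Dice overlap coefficient between two voxel masks
#'
#' `2|A n B| / (|A| + |B|)`; returns `NaN` when both masks are empty.
#'
#' @param a,b logical arrays or index vectors on the same grid.
#' @export
dice_coefficient <- function(a, b) {
  if (is.array(a)) a <- which(a)
  if (is.array(b)) b <- which(b)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}
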