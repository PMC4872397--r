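#' Read volumetric maps from NIfTI files
#'
#' Reads one 3D NIfTI volume per path, or a single 4D stack, into a
#' [map_set()]. All volumes must share one grid; subject identifiers default
#' to the file base names (volume index for a 4D stack).
#'
#' @param paths character vector of NIfTI file paths (`.nii` or `.nii.gz`).
#' @param subject_id optional identifiers overriding the defaults.
#' @return A [map_set()].
#' @export
read_maps <- function(paths, subject_id = NULL) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) abort(paste("file not found:", paste(missing, collapse = ", ")),
                             class = "spareatlas_io_error")
  vols <- list()
  ids <- character()
  for (p in paths) {
    img <- RNifti::readNifti(p)
    d <- dim(img)
    if (length(d) == 4) {
      for (k in seq_len(d[4])) {
        vols[[length(vols) + 1L]] <- array(img[, , , k], dim = d[1:3])
        ids <- c(ids, sprintf("%s_%03d", sub("\\.nii(\\.gz)?$", "", basename(p)), k))
      }
    } else if (length(d) == 3) {
      vols[[length(vols) + 1L]] <- array(as.vector(img), dim = d)
      ids <- c(ids, sub("\\.nii(\\.gz)?$", "", basename(p)))
    } else {
      abort(paste("expected a 3D or 4D volume:", p), class = "spareatlas_shape_error")
    }
  }
  shapes <- unique(lapply(vols, dim))
  if (length(shapes) != 1)
    abort("maps do not share one grid", class = "spareatlas_shape_error")
  if (!all(vapply(vols, function(v) all(is.finite(v)), logical(1))))
    abort("non-finite voxel values in input maps", class = "spareatlas_validation_error")
  map_set(vols, subject_id = subject_id %||% ids)
}

#' Write volumetric maps as NIfTI files
#'
#' Writes one compressed single-precision NIfTI file per subject (named
#' `<subject_id>.nii.gz`), or a single 4D stack when `stack` names a file.
#'
#' @param maps a [map_set()].
#' @param dir output directory, created if needed.
#' @param stack optional filename for a single 4D stack instead of per-subject
#'   files.
#' @return Invisibly, the written paths.
#' @export
write_maps <- function(maps, dir, stack = NULL) {
  stopifnot(inherits(maps, "map_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(stack)) {
    arr <- array(t(maps$values), dim = c(maps$grid, n_maps(maps)))
    path <- file.path(dir, stack)
    RNifti::writeNifti(arr, path, datatype = "float")
    return(invisible(path))
  }
  paths <- vapply(seq_len(n_maps(maps)), function(i) {
    path <- file.path(dir, paste0(maps$subject_id[i], ".nii.gz"))
    RNifti::writeNifti(map_array(maps, i), path, datatype = "float")
    path
  }, character(1))
  invisible(paths)
}

#' Read and write binary voxel masks
#'
#' Masks are stored as uint8 NIfTI volumes (1 = inside).
#'
#' @param path NIfTI file path.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.vector(img) != 0, dim = dim(img))
}

#' @rdname read_mask
#' @param mask logical 3D array.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  RNifti::writeNifti(array(as.integer(mask), dim = dim(mask)), path, datatype = "uint8")
  invisible(path)
}
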