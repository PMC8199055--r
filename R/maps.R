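#' Scalar parametric map
#'
#' A 3D scalar volume (MD in 10^-3 mm^2/s or dimensionless MK) on a voxel
#' grid.  Voxels where no estimate exists (outside the brain mask, or where
#' the fit failed) carry `NA`, which maps to NaN in NIfTI output.
#'
#' @param values numeric 3D array.
#' @param kind `"MD"` or `"MK"`.
#' @param grid a [vox_grid()].
#' @return an object of class `parametric_map`.
#' @export
parametric_map <- function(values, kind = c("MD", "MK"), grid) {
  kind <- match.arg(kind)
  values <- as.array(values)
  stopifnot(inherits(grid, "vox_grid"), length(dim(values)) == 3L)
  if (!identical(dim(values), as.integer(grid$shape)))
    stop("map shape does not match grid", call. = FALSE)
  structure(list(values = values, kind = kind, grid = grid),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat("<parametric_map:", x$kind, "> ", format(x$grid), ", ",
      length(v), " valid voxels",
      if (length(v)) sprintf(", range [%.3g, %.3g]", min(v), max(v)), "\n",
      sep = "")
  invisible(x)
}

#' Binary segmentation mask
#'
#' @param values logical (or 0/1) 3D array.
#' @param grid a [vox_grid()].
#' @param provenance one of `"auto"`, `"manual"`, `"truth"`.
#' @return an object of class `seg_mask`.
#' @export
seg_mask <- function(values, grid, provenance = c("auto", "manual", "truth")) {
  provenance <- match.arg(provenance)
  values <- as.array(values)
  stopifnot(inherits(grid, "vox_grid"), length(dim(values)) == 3L)
  if (!identical(dim(values), as.integer(grid$shape)))
    stop("mask shape does not match grid", call. = FALSE)
  if (!is.logical(values)) {
    if (!all(values %in% c(0, 1)))
      stop("mask values must be binary", call. = FALSE)
    values <- array(values > 0, dim = dim(values))
  }
  if (anyNA(values)) stop("mask must not contain NA", call. = FALSE)
  structure(list(values = values, grid = grid, provenance = provenance),
            class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  cat("<seg_mask:", x$provenance, "> ", format(x$grid), ", ",
      sum(x$values), " voxels set\n", sep = "")
  invisible(x)
}
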