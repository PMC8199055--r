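#' Voxel grid geometry
#'
#' A grid couples an array shape with a voxel-to-world affine (NIfTI
#' convention: world coordinates in mm are `affine %*% c(i, j, k, 1)` with
#' 0-based voxel indices).  By default the grid is axis-aligned and centred on
#' the world origin, so grids with different resolutions covering the same
#' field of view share a common world space and can be resampled into one
#' another.
#'
#' @param shape integer length-3 array dimensions.
#' @param voxel_size numeric length-3 voxel edge lengths in mm.
#' @param affine optional 4x4 voxel-to-world matrix; when missing, a diagonal
#'   affine centring the grid on the world origin is constructed.
#' @return an object of class `vox_grid` with elements `shape`, `voxel_size`
#'   and `affine`.
#' @export
vox_grid <- function(shape, voxel_size, affine = NULL) {
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(shape) == 3L, all(shape >= 1L), length(voxel_size) == 3L,
            all(voxel_size > 0))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
    # centre of the field of view at the world origin
    affine[1:3, 4] <- -voxel_size * (shape - 1) / 2
  }
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps)
    stop("grid affine is not invertible", call. = FALSE)
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine),
            class = "vox_grid")
}

#' @export
print.vox_grid <- function(x, ...) {
  cat("<vox_grid> ", paste(x$shape, collapse = " x "),
      " voxels @ ", paste(format(x$voxel_size), collapse = " x "), " mm\n",
      sep = "")
  invisible(x)
}

#' @export
format.vox_grid <- function(x, ...) {
  paste0(paste(x$shape, collapse = "x"), "@",
         paste(format(x$voxel_size, trim = TRUE), collapse = "x"), "mm")
}

grids_identical <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

# 0-based voxel indices of every voxel, as an n x 3 matrix (column-major order)
grid_voxel_indices <- function(grid) {
  idx <- arrayInd(seq_len(prod(grid$shape)), grid$shape)
  idx - 1L
}

# world coordinates (n x 3) of 0-based voxel indices (n x 3)
voxel_to_world <- function(grid, ijk) {
  ijk <- rbind(t(ijk), 1)
  t(grid$affine %*% ijk)[, 1:3, drop = FALSE]
}

# continuous 0-based voxel indices (n x 3) of world coordinates (n x 3)
world_to_voxel <- function(grid, xyz) {
  xyz <- rbind(t(xyz), 1)
  t(solve(grid$affine) %*% xyz)[, 1:3, drop = FALSE]
}

# world coordinates of every voxel centre of a grid, n x 3
grid_world_centers <- function(grid) {
  voxel_to_world(grid, grid_voxel_indices(grid))
}
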