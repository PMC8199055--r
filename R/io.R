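# NIfTI-1 reading and writing (via RNifti) plus FSL-dialect gradient tables.

nifti_from_grid <- function(values, grid) {
  im <- RNifti::asNifti(values)
  RNifti::pixdim(im) <- grid$voxel_size
  aff <- structure(grid$affine, code = 2L)
  RNifti::`sform<-`(im, aff)
}

grid_from_nifti <- function(im) {
  aff <- unclass(RNifti::xform(im))
  attributes(aff) <- list(dim = dim(aff))
  shape <- dim(im)[1:3]
  vs <- RNifti::pixdim(im)[1:3]
  vox_grid(shape, vs, affine = aff)
}

#' Write / read a parametric map as NIfTI-1
#'
#' Maps are stored as float32 with the grid affine in the sform; invalid
#' voxels are stored as NaN and read back as `NA`.
#'
#' @param map a [parametric_map()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `write_map` returns `path` invisibly; `read_map` returns a
#'   [parametric_map()].
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "parametric_map"))
  vals <- map$values
  vals[is.na(vals)] <- NaN
  RNifti::writeNifti(nifti_from_grid(vals, map$grid), path,
                     datatype = "float")
  invisible(path)
}

#' @rdname write_map
#' @param kind `"MD"` or `"MK"` for the map being read.
#' @export
read_map <- function(path, kind = c("MD", "MK")) {
  kind <- match.arg(kind)
  im <- RNifti::readNifti(path)
  if (length(dim(im)) != 3L)
    stop("expected a 3D map in ", path, call. = FALSE)
  vals <- as.array(im)
  vals[is.nan(vals)] <- NA_real_
  parametric_map(vals, kind, grid_from_nifti(im))
}

#' Write / read a segmentation mask as NIfTI-1
#'
#' Masks are stored as uint8 (0/1).  Reading a file with values other than
#' 0/1 is an error.
#'
#' @param mask a [seg_mask()].
#' @param path output `.nii` / `.nii.gz` path.
#' @param provenance provenance tag to attach on read.
#' @return `write_mask` returns `path` invisibly; `read_mask` returns a
#'   [seg_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "seg_mask"))
  vals <- array(as.integer(mask$values), dim = dim(mask$values))
  RNifti::writeNifti(nifti_from_grid(vals, mask$grid), path,
                     datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, provenance = "manual") {
  im <- RNifti::readNifti(path)
  if (length(dim(im)) != 3L)
    stop("expected a 3D mask in ", path, call. = FALSE)
  vals <- as.array(im)
  if (!all(vals %in% c(0, 1)))
    stop("mask file ", path, " contains non-binary values", call. = FALSE)
  seg_mask(vals > 0, grid_from_nifti(im), provenance)
}

#' Write a DWI series with its gradient table
#'
#' Writes the 4D signal as float32 NIfTI-1 plus FSL-dialect sidecars: a
#' `.bval` file with one whitespace-separated row of per-volume b-values and
#' a `.bvec` file with three rows (x, y, z gradient components per volume).
#'
#' @param dwi a `dwi_volume`.
#' @param prefix output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec`.
#' @return the three paths, invisibly.
#' @export
write_dwi <- function(dwi, prefix) {
  stopifnot(inherits(dwi, "dwi_volume"))
  nii <- paste0(prefix, ".nii.gz")
  im <- RNifti::asNifti(dwi$signal)
  RNifti::pixdim(im) <- c(dwi$grid$voxel_size, 1)
  im <- RNifti::`sform<-`(im, structure(dwi$grid$affine, code = 2L))
  RNifti::writeNifti(im, nii, datatype = "float")
  bval <- paste0(prefix, ".bval")
  bvec <- paste0(prefix, ".bvec")
  writeLines(paste(format(dwi$scheme$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval)
  writeLines(apply(dwi$scheme$bvecs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 15, scientific = FALSE),
          collapse = " ")), bvec)
  invisible(c(nii = nii, bval = bval, bvec = bvec))
}

#' Read a DWI series with its gradient table
#'
#' Reads a 4D NIfTI plus FSL-dialect `.bval`/`.bvec` sidecars and assembles
#' the acquisition scheme.  b-values are rounded to the nearest integer
#' s/mm^2; nonzero gradient vectors must be unit length within 1e-3 (they
#' are renormalised exactly); volume counts must agree across the three
#' files.
#'
#' @param nifti_path 4D DWI NIfTI file.
#' @param bval_path,bvec_path FSL-dialect gradient table files.
#' @return a `dwi_volume`.
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path) {
  for (p in c(nifti_path, bval_path, bvec_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  im <- RNifti::readNifti(nifti_path)
  if (length(dim(im)) != 4L)
    stop("expected a 4D DWI volume in ", nifti_path, call. = FALSE)
  n_vol <- dim(im)[4]

  bvals <- scan(bval_path, quiet = TRUE)
  bvals <- round(bvals)
  bvec_rows <- lapply(readLines(bvec_path), function(l)
    scan(text = l, quiet = TRUE))
  bvec_rows <- bvec_rows[vapply(bvec_rows, length, integer(1)) > 0]
  if (length(bvec_rows) != 3L)
    stop("bvec file must have 3 rows (x, y, z)", call. = FALSE)
  bvecs <- do.call(rbind, bvec_rows)
  if (length(bvals) != n_vol || ncol(bvecs) != n_vol)
    stop(sprintf(paste("volume count mismatch: %d volumes, %d b-values,",
                       "%d gradient vectors"),
                 n_vol, length(bvals), ncol(bvecs)), call. = FALSE)

  norms <- sqrt(colSums(bvecs^2))
  nz <- bvals > 0
  if (any(abs(norms[nz] - 1) > 1e-3))
    stop("non-unit gradient vectors beyond tolerance 1e-3", call. = FALSE)
  bvecs[, nz] <- sweep(bvecs[, nz, drop = FALSE], 2, norms[nz], `/`)
  bvecs[, !nz] <- 0

  scheme <- new_scheme(bvals, bvecs, infer_dir_index(bvals, bvecs))
  grid <- grid_from_nifti(im)
  new_dwi_volume(array(as.numeric(im), dim(im)), grid, scheme)
}

#' Serialise an occupancy mask or signature region to CSV
#'
#' Long format: one row per bin with its edge coordinates and flag, so the
#' file is self-describing and roundtrips exactly.
#'
#' @param x an `occupancy_mask` or `signature_region`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_occupancy_csv <- function(x, path) {
  stopifnot(inherits(x, "occupancy_mask") || inherits(x, "signature_region"))
  flags <- if (inherits(x, "occupancy_mask")) x$mask else x$region
  n_md <- nrow(flags); n_mk <- ncol(flags)
  df <- data.frame(
    md_bin = rep(seq_len(n_md), times = n_mk),
    mk_bin = rep(seq_len(n_mk), each = n_md),
    md_lo = rep(x$md_edges[-length(x$md_edges)], times = n_mk),
    md_hi = rep(x$md_edges[-1], times = n_mk),
    mk_lo = rep(x$mk_edges[-length(x$mk_edges)], each = n_md),
    mk_hi = rep(x$mk_edges[-1], each = n_md),
    flag = as.integer(as.vector(flags))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occupancy_csv
#' @param as one of `"occupancy"` or `"region"` — the class to rebuild.
#' @export
read_occupancy_csv <- function(path, as = c("occupancy", "region")) {
  as <- match.arg(as)
  df <- utils::read.csv(path)
  n_md <- max(df$md_bin); n_mk <- max(df$mk_bin)
  flags <- matrix(FALSE, n_md, n_mk)
  flags[cbind(df$md_bin, df$mk_bin)] <- df$flag > 0
  md_edges <- c(df$md_lo[df$mk_bin == 1], df$md_hi[df$mk_bin == 1][n_md])
  mk_edges <- c(df$mk_lo[df$md_bin == 1], df$mk_hi[df$md_bin == 1][n_mk])
  if (as == "occupancy")
    structure(list(mask = flags, md_edges = md_edges, mk_edges = mk_edges,
                   tau = NA_real_, dilate = NA_integer_,
                   n_subjects = NA_integer_, n_total = NA_integer_),
              class = "occupancy_mask")
  else
    structure(list(region = flags, bounds = NULL,
                   md_edges = md_edges, mk_edges = mk_edges),
              class = "signature_region")
}
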