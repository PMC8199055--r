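#' Default phantom tissue parameters
#'
#' Per-class ground-truth diffusion parameters for the synthetic brain
#' phantom: mean diffusivity MD (10^-3 mm^2/s), mean kurtosis MK
#' (dimensionless), within-class jitter standard deviations, and the
#' non-diffusion-weighted signal amplitude S0 (arbitrary units).  The healthy
#' classes reproduce the inverse MK-MD trend of normal brain (white matter
#' high-MK/low-MD through CSF low-MK/high-MD), while the tumor core and
#' infiltrative rim sit below that trend, off the healthy MK-MD manifold —
#' the configuration in which a glioma-specific diffusion signature exists.
#' Values are typical literature magnitudes for 3T DKI.
#'
#' @return a data.frame with one row per tissue class (`class` is the integer
#'   label used in phantom label volumes; 0 is background).
#' @export
default_tissue_table <- function() {
  data.frame(
    class   = 1:5,
    name    = c("wm", "gm", "csf", "tumor_core", "tumor_rim"),
    md_mean = c(0.80, 1.00, 3.00, 1.30, 1.10),
    mk_mean = c(1.00, 0.70, 0.15, 0.45, 0.55),
    md_sd   = c(0.01, 0.01, 0.03, 0.01, 0.01),
    mk_sd   = c(0.01, 0.01, 0.01, 0.01, 0.01),
    s0_mean = c(95, 100, 160, 115, 105),
    stringsAsFactors = FALSE
  )
}

#' Default phantom geometry
#'
#' Nested compartments in world millimetres, rendered by first-match
#' priority: tumor core (sphere, 12 mm), infiltrative rim (shell to 16 mm,
#' i.e. a whole-tumor sphere of radius 16 mm = 8 in-plane voxels on the
#' default DKI grid), a central CSF ellipsoid standing in for the
#' ventricles, a cortical gray-matter shell, and a white-matter interior,
#' all inside a brain ellipsoid.  Defining the geometry in world
#' coordinates lets the same anatomy be rendered on both the coarse DKI
#' grid and the finer anatomical grid without resampling.
#'
#' @param include_tumor render the tumor compartments (set `FALSE` for a
#'   healthy-control phantom).
#' @return a list of compartment descriptions, in priority order.
#' @export
default_geometry <- function(include_tumor = TRUE) {
  tumor_center <- c(28, -16, 0)
  comps <- list(
    list(name = "tumor_core", type = "ellipsoid", center = tumor_center,
         semi = c(12, 12, 12)),
    list(name = "tumor_rim", type = "ellipsoid_shell", center = tumor_center,
         semi_outer = c(16, 16, 16), semi_inner = c(12, 12, 12)),
    list(name = "csf", type = "ellipsoid", center = c(0, 0, 5),
         semi = c(14, 10, 12)),
    list(name = "gm", type = "ellipsoid_shell", center = c(0, 0, 0),
         semi_outer = c(56, 56, 50), semi_inner = c(46, 46, 41)),
    list(name = "wm", type = "ellipsoid", center = c(0, 0, 0),
         semi = c(46, 46, 41))
  )
  if (!include_tumor)
    comps <- comps[!vapply(comps, function(c.)
      startsWith(c.$name, "tumor"), logical(1))]
  comps
}

#' Phantom specification
#'
#' Describes a synthetic DKI brain phantom: the coarse DKI grid and the finer
#' anatomical grid (defaults reproduce the slice-thickness mismatch between a
#' 2 x 2 x 5 mm DKI acquisition and 1 x 1 x 3 mm anatomical imaging), the
#' per-class tissue parameters, the compartment geometry, the b = 0
#' signal-to-noise ratio and the RNG seed.  Validation enforces positive MD,
#' nonnegative MK, and a minimum separation between every tumor class and
#' every healthy class in normalised MK-MD space (MD/3.5, MK/3.0 — the
#' default histogram ranges), so that a signature region can exist.
#'
#' @param grid_shape DKI grid dimensions (voxels).
#' @param voxel_size DKI voxel size, mm.
#' @param anat_voxel_size anatomical-grid voxel size, mm (grid shape is
#'   derived so both grids cover the same field of view).
#' @param tissue_table see [default_tissue_table()].
#' @param geometry see [default_geometry()].
#' @param include_tumor used when `geometry` is not supplied.
#' @param snr b = 0 signal-to-noise ratio (`Inf` for noiseless).
#' @param seed integer RNG seed.
#' @param min_separation minimum tumor-to-healthy distance in normalised
#'   MK-MD space.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 24),
                         voxel_size = c(2, 2, 5),
                         anat_voxel_size = c(1, 1, 3),
                         tissue_table = default_tissue_table(),
                         geometry = default_geometry(include_tumor),
                         include_tumor = TRUE,
                         snr = 40,
                         seed = 1L,
                         min_separation = 0.05) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4),
            length(voxel_size) == 3L, all(voxel_size > 0),
            length(anat_voxel_size) == 3L, all(anat_voxel_size > 0),
            is.numeric(snr), length(snr) == 1L, snr > 0,
            length(seed) == 1L)
  tt <- tissue_table
  req <- c("class", "name", "md_mean", "mk_mean", "md_sd", "mk_sd", "s0_mean")
  if (!all(req %in% names(tt)))
    stop("tissue_table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(tt$md_mean <= 0)) stop("all MD_mean must be > 0", call. = FALSE)
  if (any(tt$mk_mean < 0)) stop("all MK_mean must be >= 0", call. = FALSE)
  if (any(tt$md_sd < 0) || any(tt$mk_sd < 0))
    stop("jitter sds must be >= 0", call. = FALSE)
  if (any(tt$s0_mean <= 0)) stop("all S0_mean must be > 0", call. = FALSE)

  tumor <- grepl("^tumor", tt$name)
  if (any(tumor) && any(!tumor)) {
    # separation in normalised MK-MD space between tumor and healthy classes
    nd <- outer(tt$md_mean[tumor] / 3.5, tt$md_mean[!tumor] / 3.5, "-")^2 +
          outer(tt$mk_mean[tumor] / 3.0, tt$mk_mean[!tumor] / 3.0, "-")^2
    if (min(sqrt(nd)) < min_separation)
      stop(sprintf(paste("tumor and healthy classes are closer than",
                         "min_separation = %g in normalised MK-MD space"),
                   min_separation), call. = FALSE)
  }

  anat_shape <- as.integer(round(grid_shape * voxel_size / anat_voxel_size))
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 anat_voxel_size = as.numeric(anat_voxel_size),
                 anat_grid_shape = anat_shape,
                 tissue_table = tt,
                 geometry = geometry,
                 snr = snr,
                 seed = as.integer(seed),
                 min_separation = min_separation),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> DKI ", paste(x$grid_shape, collapse = "x"), " @ ",
      paste(x$voxel_size, collapse = "x"), " mm; anat ",
      paste(x$anat_grid_shape, collapse = "x"), " @ ",
      paste(x$anat_voxel_size, collapse = "x"), " mm; snr = ", x$snr,
      "; seed = ", x$seed, "\n", sep = "")
  cat("  classes:", paste(x$tissue_table$name, collapse = ", "), "\n")
  invisible(x)
}

compartment_member <- function(comp, xyz) {
  d2 <- function(center, semi) {
    ((xyz[, 1] - center[1]) / semi[1])^2 +
    ((xyz[, 2] - center[2]) / semi[2])^2 +
    ((xyz[, 3] - center[3]) / semi[3])^2
  }
  switch(comp$type,
    ellipsoid = d2(comp$center, comp$semi) <= 1,
    ellipsoid_shell = d2(comp$center, comp$semi_outer) <= 1 &
                      d2(comp$center, comp$semi_inner) > 1,
    stop("unknown compartment type: ", comp$type, call. = FALSE))
}

# First-match-wins rendering of the compartment list onto a grid.
render_labels <- function(geometry, grid, tissue_table) {
  xyz <- grid_world_centers(grid)
  labels <- integer(nrow(xyz))
  class_of <- stats::setNames(tissue_table$class, tissue_table$name)
  for (comp in geometry) {
    if (!comp$name %in% names(class_of))
      stop("geometry compartment '", comp$name, "' not in tissue_table",
           call. = FALSE)
    hit <- labels == 0L & compartment_member(comp, xyz)
    labels[hit] <- class_of[[comp$name]]
  }
  array(labels, dim = grid$shape)
}

#' Build a phantom: geometry, ground-truth maps, masks
#'
#' Renders the compartment geometry on the DKI grid and, independently, on
#' the anatomical grid (same world-space geometry at both resolutions — the
#' anatomical masks are *rendered*, not resampled).  Per-voxel ground-truth
#' MD and MK are the class means plus seeded Gaussian jitter (clamped to
#' MD > 0, MK >= 0); S0 is piecewise constant.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_truth` with `label_volume`,
#'   `md_truth`, `mk_truth`, `s0_truth` (3D arrays on the DKI grid),
#'   `brain_mask`, `tumor_mask_dki` ([seg_mask()]s on the DKI grid),
#'   `tumor_mask_anat`, `brain_mask_anat` (on the anatomical grid), and the
#'   two grids.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- vox_grid(spec$grid_shape, spec$voxel_size)
  anat_grid <- vox_grid(spec$anat_grid_shape, spec$anat_voxel_size)
  tt <- spec$tissue_table

  labels <- render_labels(spec$geometry, grid, tt)
  has_tumor <- any(vapply(spec$geometry, function(c.)
    startsWith(c.$name, "tumor"), logical(1)))
  tumor_classes <- tt$class[grepl("^tumor", tt$name)]
  if (has_tumor && !any(labels %in% tumor_classes))
    stop("tumor compartment rendered to 0 voxels", call. = FALSE)

  n <- prod(spec$grid_shape)
  md <- mk <- s0 <- numeric(n)
  set.seed(spec$seed)
  for (r in seq_len(nrow(tt))) {
    idx <- which(labels == tt$class[r])
    if (!length(idx)) next
    md[idx] <- pmax(tt$md_mean[r] + stats::rnorm(length(idx), 0, tt$md_sd[r]),
                    1e-6)
    mk[idx] <- pmax(tt$mk_mean[r] + stats::rnorm(length(idx), 0, tt$mk_sd[r]),
                    0)
    s0[idx] <- tt$s0_mean[r]
  }
  dim(md) <- dim(mk) <- dim(s0) <- spec$grid_shape

  labels_anat <- render_labels(spec$geometry, anat_grid, tt)
  structure(list(
    spec = spec,
    grid = grid,
    anat_grid = anat_grid,
    label_volume = labels,
    md_truth = md,
    mk_truth = mk,
    s0_truth = s0,
    brain_mask = seg_mask(labels > 0L, grid, "truth"),
    tumor_mask_dki = seg_mask(array(labels %in% tumor_classes,
                                    dim = spec$grid_shape), grid, "truth"),
    brain_mask_anat = seg_mask(labels_anat > 0L, anat_grid, "truth"),
    tumor_mask_anat = seg_mask(array(labels_anat %in% tumor_classes,
                                     dim = spec$anat_grid_shape),
                               anat_grid, "truth")
  ), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth> ", format(x$grid), "; brain ",
      sum(x$brain_mask$values), " voxels; tumor ",
      sum(x$tumor_mask_dki$values), " voxels (DKI grid)\n", sep = "")
  invisible(x)
}
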