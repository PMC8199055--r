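#' Resample a map or mask onto another grid
#'
#' World-coordinate pull-back resampling: each target voxel centre is mapped
#' through the target affine into world space and through the inverse source
#' affine into continuous source voxel coordinates, where the source is
#' sampled with nearest-neighbour or trilinear interpolation.  Masks may
#' only use nearest-neighbour (label integrity); scalar maps may use either.
#' Target voxels falling outside the source field of view become invalid
#' (`NA`) for maps and `FALSE` for masks.  Nearest-neighbour ties are broken
#' upward (`floor(x + 0.5)`), not by banker's rounding, so integer-ratio
#' aligned grids resample reproducibly.
#'
#' @param source a [parametric_map()] or [seg_mask()].
#' @param target_grid a [vox_grid()] sharing the source's world space.
#' @param method `"nearest"` or `"trilinear"`.
#' @return the same kind of object on `target_grid`.
#' @export
resample_to_grid <- function(source, target_grid,
                             method = c("nearest", "trilinear")) {
  method <- match.arg(method)
  is_mask <- inherits(source, "seg_mask")
  if (!is_mask && !inherits(source, "parametric_map"))
    stop("source must be a parametric_map or seg_mask", call. = FALSE)
  stopifnot(inherits(target_grid, "vox_grid"))
  if (is_mask && method == "trilinear")
    stop("masks must be resampled with method = \"nearest\"", call. = FALSE)
  if (grids_identical(source$grid, target_grid)) return(source)

  # continuous 0-based source indices of all target voxel centres
  M <- solve(source$grid$affine) %*% target_grid$affine
  ijk_t <- grid_voxel_indices(target_grid)
  ci <- t(M %*% rbind(t(ijk_t), 1))[, 1:3, drop = FALSE]
  d <- source$grid$shape
  src <- if (is_mask) source$values else source$values

  if (method == "nearest") {
    ni <- floor(ci + 0.5)
    ok <- ni[, 1] >= 0 & ni[, 1] < d[1] &
          ni[, 2] >= 0 & ni[, 2] < d[2] &
          ni[, 3] >= 0 & ni[, 3] < d[3]
    out <- rep(if (is_mask) FALSE else NA_real_, nrow(ni))
    lin <- ni[ok, 3] * (d[1] * d[2]) + ni[ok, 2] * d[1] + ni[ok, 1] + 1
    out[ok] <- src[lin]
  } else {
    f0 <- floor(ci)
    fr <- ci - f0
    ok <- f0[, 1] >= 0 & f0[, 1] + 1 <= d[1] - 1 &
          f0[, 2] >= 0 & f0[, 2] + 1 <= d[2] - 1 &
          f0[, 3] >= 0 & f0[, 3] + 1 <= d[3] - 1
    out <- rep(NA_real_, nrow(ci))
    if (any(ok)) {
      f <- f0[ok, , drop = FALSE]
      w <- fr[ok, , drop = FALSE]
      acc <- 0
      for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
        lin <- (f[, 3] + cz) * (d[1] * d[2]) + (f[, 2] + cy) * d[1] +
               (f[, 1] + cx) + 1
        wt <- (if (cx == 1) w[, 1] else 1 - w[, 1]) *
              (if (cy == 1) w[, 2] else 1 - w[, 2]) *
              (if (cz == 1) w[, 3] else 1 - w[, 3])
        acc <- acc + wt * src[lin]
      }
      out[ok] <- acc
    }
  }
  vals <- array(out, target_grid$shape)
  if (is_mask) seg_mask(vals, target_grid, source$provenance)
  else parametric_map(vals, source$kind, target_grid)
}

#' Dice similarity coefficient of two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`.  The masks must already live on the
#' same grid — no silent resampling.  If both masks are empty the
#' coefficient is defined as 1.0 and a warning makes the degeneracy visible.
#'
#' @param a,b [seg_mask()]s on identical grids.
#' @return the Dice coefficient, in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "seg_mask"), inherits(b, "seg_mask"))
  if (!grids_identical(a$grid, b$grid))
    stop("masks are on different grids: resample explicitly before dice()",
         call. = FALSE)
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0L) {
    warning("both masks are empty: Dice defined as 1.0", call. = FALSE)
    return(1.0)
  }
  2 * sum(a$values & b$values) / (na + nb)
}

#' Overlap report for an automatic vs. reference segmentation
#'
#' @param auto automatic [seg_mask()].
#' @param ref reference (e.g. manual or ground-truth) [seg_mask()] on the
#'   same grid.
#' @param subgroup_label free-text group label carried into reports (e.g. a
#'   molecular subgroup name).
#' @param case_id free-text case identifier.
#' @return a one-row data.frame with columns `case_id`, `subgroup_label`,
#'   `n_auto`, `n_ref`, `n_intersection`, `dice`, `grid_id`.
#' @export
overlap_report <- function(auto, ref, subgroup_label = NA_character_,
                           case_id = NA_character_) {
  d <- dice(auto, ref)
  data.frame(case_id = case_id,
             subgroup_label = subgroup_label,
             n_auto = sum(auto$values),
             n_ref = sum(ref$values),
             n_intersection = sum(auto$values & ref$values),
             dice = d,
             grid_id = format(auto$grid),
             stringsAsFactors = FALSE)
}

#' Aggregate overlap reports by subgroup
#'
#' Per-subgroup mean Dice plus a global average row, mirroring a per-group
#' overlap summary table.
#'
#' @param reports a data.frame of stacked [overlap_report()] rows.
#' @return a data.frame with columns `subgroup_label`, `n_cases`,
#'   `mean_dice`.
#' @export
aggregate_overlap <- function(reports) {
  stopifnot(is.data.frame(reports), all(c("subgroup_label", "dice") %in%
                                        names(reports)))
  groups <- split(reports$dice, reports$subgroup_label)
  out <- data.frame(
    subgroup_label = names(groups),
    n_cases = vapply(groups, length, integer(1)),
    mean_dice = vapply(groups, mean, numeric(1)),
    stringsAsFactors = FALSE
  )
  out <- rbind(out, data.frame(subgroup_label = "average",
                               n_cases = nrow(reports),
                               mean_dice = mean(reports$dice)))
  rownames(out) <- NULL
  out
}
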