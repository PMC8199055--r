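#' Default MK-MD histogram binning
#'
#' Fixed bin edges for the joint MK-MD feature space: MD from 0 to
#' 3.5 x 10^-3 mm^2/s in steps of 0.05, MK from 0 to 3.0 in steps of 0.02.
#' Fixed (rather than data-driven) edges make occupancy masks from different
#' subjects directly comparable.
#'
#' @param md_max,md_step,mk_max,mk_step edge parameters.
#' @return a list with `md_edges` and `mk_edges`.
#' @export
default_binning <- function(md_max = 3.5, md_step = 0.05,
                            mk_max = 3.0, mk_step = 0.02) {
  list(md_edges = seq(0, md_max, by = md_step),
       mk_edges = seq(0, mk_max, by = mk_step))
}

bin_index <- function(x, edges) {
  # bin i covers [edges[i], edges[i+1]); the last bin is closed on the right;
  # 0 marks out-of-range
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[i >= length(edges)] <- 0L
  i
}

#' Joint MK-MD histogram of a parametric-map pair
#'
#' Bins the (MD, MK) values of all masked, valid voxels onto the fixed 2D
#' lattice — the binned counterpart of the whole-brain MK-vs-MD scatter
#' plot.  Voxels with an invalid marker in either map are excluded and
#' counted separately; in-mask voxels falling outside the edge range are
#' counted as out-of-range.
#'
#' @param md,mk [parametric_map()]s on a common grid.
#' @param mask a [seg_mask()] on the same grid.
#' @param binning see [default_binning()].
#' @param source_id free-text provenance label.
#' @return an object of class `joint_histogram`: integer `counts`
#'   (MD bins x MK bins), the edges, `n_total` (= sum(counts) +
#'   `n_out_of_range`), `n_invalid`, `source_id`.
#' @export
joint_histogram <- function(md, mk, mask, binning = default_binning(),
                            source_id = "") {
  stopifnot(inherits(md, "parametric_map"), inherits(mk, "parametric_map"),
            inherits(mask, "seg_mask"))
  if (!grids_identical(md$grid, mk$grid) ||
      !grids_identical(md$grid, mask$grid))
    stop("maps and mask must share a grid", call. = FALSE)
  stopifnot(!is.unsorted(binning$md_edges, strictly = TRUE),
            !is.unsorted(binning$mk_edges, strictly = TRUE))

  sel <- mask$values
  mdv <- md$values[sel]; mkv <- mk$values[sel]
  invalid <- is.na(mdv) | is.na(mkv)
  mdv <- mdv[!invalid]; mkv <- mkv[!invalid]

  n_md <- length(binning$md_edges) - 1L
  n_mk <- length(binning$mk_edges) - 1L
  i <- bin_index(mdv, binning$md_edges)
  j <- bin_index(mkv, binning$mk_edges)
  in_range <- i > 0L & j > 0L
  counts <- matrix(0L, n_md, n_mk)
  if (any(in_range)) {
    tab <- tabulate((j[in_range] - 1L) * n_md + i[in_range], n_md * n_mk)
    counts <- matrix(as.integer(tab), n_md, n_mk)
  }
  structure(list(counts = counts,
                 md_edges = binning$md_edges, mk_edges = binning$mk_edges,
                 n_total = length(mdv),
                 n_out_of_range = sum(!in_range),
                 n_invalid = sum(invalid),
                 source_id = source_id),
            class = "joint_histogram")
}

#' @export
print.joint_histogram <- function(x, ...) {
  cat("<joint_histogram> ", nrow(x$counts), " MD x ", ncol(x$counts),
      " MK bins, n = ", x$n_total, " (", x$n_out_of_range, " out of range, ",
      x$n_invalid, " invalid)\n", sep = "")
  invisible(x)
}

same_edges <- function(a, b, tol = 1e-9) {
  length(a$md_edges) == length(b$md_edges) &&
    length(a$mk_edges) == length(b$mk_edges) &&
    max(abs(a$md_edges - b$md_edges)) <= tol &&
    max(abs(a$mk_edges - b$mk_edges)) <= tol
}

#' Healthy-reference MK-MD occupancy
#'
#' Pools the joint histograms of a healthy-reference cohort and marks a bin
#' as occupied if its pooled relative frequency reaches `tau` (a bin with
#' zero pooled counts is never occupied, so `tau = 0` gives the pooled
#' support), then dilates the occupied set by `dilate` bins in Chebyshev
#' distance.  The complement of this occupancy, within physiological bounds,
#' is where a glioma-specific MK-MD combination can live.  Pooling (rather
#' than per-subject intersection) is the conservative choice: a larger
#' occupancy yields fewer false-positive signature voxels.
#'
#' @param histograms list of [joint_histogram()]s on identical edges.
#' @param tau relative-frequency threshold, >= 0 (default 1e-5).
#' @param dilate dilation radius in bins (default 1).
#' @return an object of class `occupancy_mask`: logical `mask`
#'   (MD bins x MK bins), the edges, `tau`, `dilate`, `n_subjects`,
#'   `n_total`.
#' @export
build_reference_occupancy <- function(histograms, tau = 1e-5, dilate = 1L) {
  if (inherits(histograms, "joint_histogram")) histograms <- list(histograms)
  stopifnot(length(histograms) >= 1L,
            all(vapply(histograms, inherits, logical(1), "joint_histogram")),
            is.numeric(tau), tau >= 0, dilate >= 0)
  for (h in histograms[-1])
    if (!same_edges(histograms[[1]], h))
      stop("histograms have mismatched bin edges", call. = FALSE)

  pooled <- Reduce(`+`, lapply(histograms, `[[`, "counts"))
  n <- sum(vapply(histograms, `[[`, numeric(1), "n_total"))
  occ <- pooled > 0L & (pooled / max(n, 1)) >= tau
  occ <- dilate_chebyshev(occ, as.integer(dilate))
  structure(list(mask = occ,
                 md_edges = histograms[[1]]$md_edges,
                 mk_edges = histograms[[1]]$mk_edges,
                 tau = tau, dilate = as.integer(dilate),
                 n_subjects = length(histograms), n_total = n),
            class = "occupancy_mask")
}

#' @export
print.occupancy_mask <- function(x, ...) {
  cat("<occupancy_mask> ", sum(x$mask), " of ", length(x$mask),
      " bins occupied (", x$n_subjects, " subjects, tau = ", x$tau,
      ", dilate = ", x$dilate, ")\n", sep = "")
  invisible(x)
}

# Binary dilation with a (2r+1)^2 square structuring element via shifts.
dilate_chebyshev <- function(m, r) {
  if (r == 0L || !any(m)) return(m)
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (di in -r:r) for (dj in -r:r) {
    if (di == 0L && dj == 0L) next
    si <- seq_len(nr) - di; sj <- seq_len(nc) - dj
    oi <- which(si >= 1 & si <= nr); oj <- which(sj >= 1 & sj <= nc)
    out[oi, oj] <- out[oi, oj] | m[si[oi], sj[oj]]
  }
  out
}

#' Glioma-specific signature region in MK-MD space
#'
#' The signature region is the complement of the healthy-reference
#' occupancy, intersected with physiological bounds on the bin centres
#' (defaults MD in (0.2, 3.0] x 10^-3 mm^2/s, MK in (0.1, 2.0]): the set of
#' MK-MD combinations that do not occur in healthy brain yet are
#' physically plausible tissue values.  Disjointness from the occupancy is
#' asserted by construction.
#'
#' @param occ an [build_reference_occupancy()] result.
#' @param bounds list with `md` and `mk` length-2 numeric ranges (open on
#'   the left, closed on the right).
#' @return an object of class `signature_region`: logical `region` on the
#'   bin lattice, `bounds`, and the edges.
#' @export
derive_signature_region <- function(occ,
                                    bounds = list(md = c(0.2, 3.0),
                                                  mk = c(0.1, 2.0))) {
  stopifnot(inherits(occ, "occupancy_mask"),
            is.list(bounds), length(bounds$md) == 2L, length(bounds$mk) == 2L)
  md_c <- (occ$md_edges[-1] + occ$md_edges[-length(occ$md_edges)]) / 2
  mk_c <- (occ$mk_edges[-1] + occ$mk_edges[-length(occ$mk_edges)]) / 2
  in_bounds <- outer(md_c > bounds$md[1] & md_c <= bounds$md[2],
                     mk_c > bounds$mk[1] & mk_c <= bounds$mk[2], `&`)
  if (!any(in_bounds))
    stop("physiological bounds exclude every bin", call. = FALSE)
  region <- !occ$mask & in_bounds
  stopifnot(!any(region & occ$mask))
  structure(list(region = region, bounds = bounds,
                 md_edges = occ$md_edges, mk_edges = occ$mk_edges),
            class = "signature_region")
}

#' @export
print.signature_region <- function(x, ...) {
  cat("<signature_region> ", sum(x$region), " of ", length(x$region),
      " bins\n", sep = "")
  invisible(x)
}

#' Manual MK-MD gate
#'
#' Builds a signature region directly from an explicit MD/MK rectangle,
#' mimicking visual delineation of the anomalous scatter-plot area instead
#' of the occupancy-complement construction.
#'
#' @param md_range,mk_range length-2 numeric ranges (left-open,
#'   right-closed, applied to bin centres).
#' @param binning see [default_binning()].
#' @return a `signature_region`.
#' @export
manual_gate_region <- function(md_range, mk_range,
                               binning = default_binning()) {
  stopifnot(length(md_range) == 2L, length(mk_range) == 2L)
  md_c <- (binning$md_edges[-1] +
           binning$md_edges[-length(binning$md_edges)]) / 2
  mk_c <- (binning$mk_edges[-1] +
           binning$mk_edges[-length(binning$mk_edges)]) / 2
  region <- outer(md_c > md_range[1] & md_c <= md_range[2],
                  mk_c > mk_range[1] & mk_c <= mk_range[2], `&`)
  structure(list(region = region,
                 bounds = list(md = md_range, mk = mk_range),
                 md_edges = binning$md_edges, mk_edges = binning$mk_edges),
            class = "signature_region")
}

#' Label voxels carrying the diffusion signature
#'
#' A voxel is labeled when it is inside the analysis mask, has valid MD and
#' MK estimates, and its (MD, MK) bin lies in the signature region.
#' 26-connected components smaller than `min_cluster` voxels are then
#' removed to suppress isolated noise voxels.
#'
#' @param md,mk [parametric_map()]s on a common grid.
#' @param mask analysis [seg_mask()] (typically the brain mask).
#' @param region a [derive_signature_region()] result.
#' @param min_cluster minimum 26-connected component size kept (default 10;
#'   0 disables the filter).
#' @return a [seg_mask()] (provenance `"auto"`) with attributes
#'   `n_before_filter` and `n_removed`.
#' @export
label_voxels <- function(md, mk, mask, region, min_cluster = 10L) {
  stopifnot(inherits(md, "parametric_map"), inherits(mk, "parametric_map"),
            inherits(mask, "seg_mask"), inherits(region, "signature_region"),
            min_cluster >= 0)
  if (!grids_identical(md$grid, mk$grid) ||
      !grids_identical(md$grid, mask$grid))
    stop("maps and mask must share a grid", call. = FALSE)

  shape <- md$grid$shape
  lab <- array(FALSE, shape)
  sel <- mask$values & !is.na(md$values) & !is.na(mk$values)
  if (any(sel)) {
    i <- bin_index(md$values[sel], region$md_edges)
    j <- bin_index(mk$values[sel], region$mk_edges)
    in_range <- i > 0L & j > 0L
    hit <- logical(sum(sel))
    hit[in_range] <- region$region[cbind(i[in_range], j[in_range])]
    lab[sel] <- hit
  }
  n_before <- sum(lab)
  n_removed <- 0L
  if (min_cluster > 0L && n_before > 0L) {
    comp <- label_components(lab)
    keep <- which(tabulate(comp$labels, comp$n) >= min_cluster)
    filtered <- array(FALSE, shape)
    filtered[comp$index[comp$labels %in% keep]] <- TRUE
    n_removed <- n_before - sum(filtered)
    lab <- filtered
  }
  out <- seg_mask(lab, md$grid, "auto")
  attr(out, "n_before_filter") <- n_before
  attr(out, "n_removed") <- n_removed
  out
}

#' 26-connected components of a 3D logical array
#'
#' Union-find over the foreground voxels with the 13 forward neighbour
#' offsets of the 26-neighbourhood.
#'
#' @param x logical 3D array.
#' @return list with `index` (linear indices of foreground voxels),
#'   `labels` (component id per foreground voxel, 1..n) and `n` (number of
#'   components).
#' @export
label_components <- function(x) {
  stopifnot(is.logical(x), length(dim(x)) == 3L)
  idx <- which(x)
  n_fg <- length(idx)
  if (n_fg == 0L) return(list(index = integer(0), labels = integer(0), n = 0L))
  d <- dim(x)
  rank_of <- integer(prod(d))
  rank_of[idx] <- seq_len(n_fg)
  coords <- arrayInd(idx, d)

  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
               (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]

  parent <- seq_len(n_fg)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (t in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[t, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1L) * (d[1] * d[2]) +
              (nb[ok, 2] - 1L) * d[1] + nb[ok, 1]
    nb_rank <- rank_of[nb_lin]
    a_rank <- which(ok)[nb_rank > 0L]
    b_rank <- nb_rank[nb_rank > 0L]
    for (e in seq_along(a_rank)) {
      ra <- find(a_rank[e]); rb <- find(b_rank[e])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n_fg), find, integer(1))
  labels <- as.integer(factor(roots))
  list(index = idx, labels = labels, n = max(labels))
}
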