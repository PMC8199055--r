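#' MK-vs-MD scatter plot with signature-region overlay
#'
#' Renders the joint MK-MD distribution of masked, valid voxels (MD on the
#' x axis in 10^-3 mm^2/s, dimensionless MK on the y axis), optionally
#' shading the healthy-reference occupancy and outlining the
#' glioma-signature region.
#'
#' @param md,mk [parametric_map()]s on a common grid.
#' @param mask a [seg_mask()].
#' @param region optional `signature_region` to overlay.
#' @param occupancy optional `occupancy_mask` to shade.
#' @param file optional PNG output path; `NULL` draws on the active device.
#' @param max_points subsample cap for the scatter.
#' @param main plot title.
#' @return the output path (or `NULL`), invisibly.
#' @export
plot_signature_scatter <- function(md, mk, mask, region = NULL,
                                   occupancy = NULL, file = NULL,
                                   max_points = 20000L,
                                   main = "MK vs MD") {
  sel <- mask$values & !is.na(md$values) & !is.na(mk$values)
  x <- md$values[sel]; y <- mk$values[sel]
  if (length(x) > max_points) {
    keep <- round(seq(1, length(x), length.out = max_points))
    x <- x[keep]; y <- y[keep]
  }
  if (!is.null(file)) grDevices::png(file, width = 900, height = 700)
  on.exit(if (!is.null(file)) grDevices::dev.off(), add = TRUE)

  graphics::plot(NA, xlim = c(0, 3.5), ylim = c(0, 2.5),
                 xlab = expression(MD ~ (10^-3 ~ mm^2 / s)), ylab = "MK",
                 main = main)
  shade_bins <- function(flags, edges_md, edges_mk, col, border = NA) {
    hit <- which(flags, arr.ind = TRUE)
    if (!nrow(hit)) return(invisible())
    graphics::rect(edges_md[hit[, 1]], edges_mk[hit[, 2]],
                   edges_md[hit[, 1] + 1], edges_mk[hit[, 2] + 1],
                   col = col, border = border)
  }
  if (!is.null(occupancy))
    shade_bins(occupancy$mask, occupancy$md_edges, occupancy$mk_edges,
               grDevices::adjustcolor("grey70", 0.5))
  if (!is.null(region))
    shade_bins(region$region, region$md_edges, region$mk_edges,
               grDevices::adjustcolor("firebrick", 0.15))
  graphics::points(x, y, pch = ".", col = grDevices::adjustcolor("navy", 0.4))
  invisible(file)
}
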