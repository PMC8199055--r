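make_map_pair <- function(md_vals, mk_vals, shape = c(4, 4, 2)) {
  grid <- vox_grid(shape, c(2, 2, 5))
  md <- parametric_map(array(md_vals, shape), "MD", grid)
  mk <- parametric_map(array(mk_vals, shape), "MK", grid)
  mask <- seg_mask(array(TRUE, shape), grid)
  list(md = md, mk = mk, mask = mask, grid = grid)
}

test_that("joint histogram conserves counts and excludes invalid voxels", {
  set.seed(1)
  n <- 4 * 4 * 2
  md_vals <- runif(n, -0.5, 4.0)        # some deliberately out of range
  mk_vals <- runif(n, -0.1, 3.5)
  md_vals[3] <- NA
  mp <- make_map_pair(md_vals, mk_vals)
  h <- joint_histogram(mp$md, mp$mk, mp$mask)
  expect_identical(sum(h$counts) + h$n_out_of_range, h$n_total)
  expect_identical(h$n_total + h$n_invalid, as.integer(n))
  expect_identical(h$n_invalid, 1L)
})

test_that("a single voxel lands in the bin found by exhaustive edge search", {
  mp <- make_map_pair(1.00, 0.50, shape = c(1, 1, 1))
  h <- joint_histogram(mp$md, mp$mk, mp$mask)
  hits <- which(h$counts > 0, arr.ind = TRUE)
  expect_identical(nrow(hits), 1L)
  # brute-force linear scan over the edges
  i_exp <- j_exp <- NA
  for (i in seq_len(length(h$md_edges) - 1))
    if (h$md_edges[i] <= 1.00 && 1.00 < h$md_edges[i + 1]) i_exp <- i
  for (j in seq_len(length(h$mk_edges) - 1))
    if (h$mk_edges[j] <= 0.50 && 0.50 < h$mk_edges[j + 1]) j_exp <- j
  expect_identical(as.vector(hits), as.integer(c(i_exp, j_exp)))
})

test_that("an empty mask produces an all-zero histogram", {
  mp <- make_map_pair(1, 1)
  empty <- seg_mask(array(FALSE, c(4, 4, 2)), mp$grid)
  h <- joint_histogram(mp$md, mp$mk, empty)
  expect_identical(sum(h$counts), 0L)
  expect_identical(h$n_total, 0L)
})

test_that("occupancy at tau = 0, dilate = 0 is the pooled support", {
  set.seed(2)
  mps <- lapply(1:2, function(i)
    make_map_pair(runif(32, 0.3, 3.2), runif(32, 0.1, 1.9)))
  hs <- lapply(mps, function(m) joint_histogram(m$md, m$mk, m$mask))
  occ <- build_reference_occupancy(hs, tau = 0, dilate = 0)
  pooled <- hs[[1]]$counts + hs[[2]]$counts
  expect_identical(occ$mask, pooled > 0)
})

test_that("rare bins fall below the frequency threshold", {
  mp <- make_map_pair(1.0, 0.5, shape = c(1, 1, 1))
  h <- joint_histogram(mp$md, mp$mk, mp$mask)
  # emulate one subject with a million-voxel scatter holding this bin once
  h$n_total <- 1000000L
  occ <- build_reference_occupancy(list(h), tau = 1e-5, dilate = 0)
  expect_false(any(occ$mask))
  occ2 <- build_reference_occupancy(list(h), tau = 1e-7, dilate = 0)
  expect_identical(sum(occ2$mask), 1L)
})

test_that("dilation monotonically enlarges occupancy, bin by bin", {
  set.seed(3)
  mp <- make_map_pair(runif(32, 0.3, 3.2), runif(32, 0.1, 1.9))
  h <- joint_histogram(mp$md, mp$mk, mp$mask)
  o0 <- build_reference_occupancy(list(h), tau = 0, dilate = 0)
  o1 <- build_reference_occupancy(list(h), tau = 0, dilate = 1)
  expect_true(all(o1$mask[o0$mask]))
  expect_gt(sum(o1$mask), sum(o0$mask))
  # every added bin is Chebyshev-adjacent to a support bin
  added <- which(o1$mask & !o0$mask, arr.ind = TRUE)
  supp <- which(o0$mask, arr.ind = TRUE)
  for (r in seq_len(nrow(added))) {
    cheb <- pmax(abs(supp[, 1] - added[r, 1]), abs(supp[, 2] - added[r, 2]))
    expect_lte(min(cheb), 1)
  }
})

test_that("signature region is the bounded complement of occupancy", {
  mp <- make_map_pair(1.0, 0.5, shape = c(1, 1, 1))
  h <- joint_histogram(mp$md, mp$mk, mp$mask)
  full <- build_reference_occupancy(list(h), tau = 0, dilate = 0)
  full$mask[] <- TRUE
  expect_identical(sum(derive_signature_region(full)$region), 0L)

  none <- full; none$mask[] <- FALSE
  reg <- derive_signature_region(none)
  # brute-force bin-centre scan of the default physiological bounds
  md_c <- (h$md_edges[-1] + h$md_edges[-length(h$md_edges)]) / 2
  mk_c <- (h$mk_edges[-1] + h$mk_edges[-length(h$mk_edges)]) / 2
  n_exp <- 0L
  for (i in seq_along(md_c)) for (j in seq_along(mk_c))
    if (md_c[i] > 0.2 && md_c[i] <= 3.0 && mk_c[j] > 0.1 && mk_c[j] <= 2.0)
      n_exp <- n_exp + 1L
  expect_identical(sum(reg$region), n_exp)

  set.seed(4)
  rnd <- full
  rnd$mask <- matrix(runif(length(full$mask)) < 0.5, nrow(full$mask))
  expect_false(any(derive_signature_region(rnd)$region & rnd$mask))
  expect_error(derive_signature_region(none,
                                       bounds = list(md = c(10, 11),
                                                     mk = c(10, 11))),
               "exclude")
})

test_that("labeled voxels back-project into the signature region only", {
  set.seed(5)
  shape <- c(8, 8, 4)
  mp <- make_map_pair(runif(prod(shape), 0.3, 3.2),
                      runif(prod(shape), 0.1, 1.9), shape)
  h <- joint_histogram(mp$md, mp$mk, mp$mask)
  occ <- build_reference_occupancy(list(h), tau = 0, dilate = 0)
  occ$mask <- matrix(runif(length(occ$mask)) < 0.6, nrow(occ$mask))
  reg <- derive_signature_region(occ)
  lab <- label_voxels(mp$md, mp$mk, mp$mask, reg, min_cluster = 0)
  sel <- lab$values
  if (any(sel)) {
    i <- kurtosig:::bin_index(mp$md$values[sel], reg$md_edges)
    j <- kurtosig:::bin_index(mp$mk$values[sel], reg$mk_edges)
    expect_true(all(reg$region[cbind(i, j)]))
  }
  # empty region labels nothing
  reg0 <- reg; reg0$region[] <- FALSE
  expect_identical(sum(label_voxels(mp$md, mp$mk, mp$mask, reg0)$values), 0L)
})

test_that("small clusters are removed, matching a flood-fill oracle", {
  shape <- c(12, 12, 6)
  grid <- vox_grid(shape, c(2, 2, 5))
  md_vals <- array(1.0, shape)          # MD 1.0 / MK 0.5 will be in-region
  mk_vals <- array(0.5, shape)
  target <- array(FALSE, shape)
  target[3:7, 3:7, 2:4] <- TRUE          # big blob: 75 voxels
  target[10, 10, 5] <- TRUE              # 3-voxel island
  target[10, 11, 5] <- TRUE
  target[11, 10, 6] <- TRUE              # 26-connected to the other two
  md_vals[!target] <- 0.1                # out of physiological bounds
  mp <- list(md = parametric_map(md_vals, "MD", grid),
             mk = parametric_map(mk_vals, "MK", grid),
             mask = seg_mask(array(TRUE, shape), grid))
  occ <- build_reference_occupancy(
    list(joint_histogram(mp$md, mp$mk, mp$mask)), tau = 2, dilate = 0)
  reg <- derive_signature_region(occ)   # occupancy empty: region = bounds

  lab5 <- label_voxels(mp$md, mp$mk, mp$mask, reg, min_cluster = 5)
  # oracle: flood fill, keep components >= 5
  ora <- oracle_flood_fill(target)
  keep <- as.integer(names(which(table(ora[ora > 0]) >= 5)))
  expect_identical(lab5$values, array(ora %in% keep, shape))
  expect_identical(attr(lab5, "n_removed"), 3L)

  lab0 <- label_voxels(mp$md, mp$mk, mp$mask, reg, min_cluster = 0)
  expect_identical(lab0$values, target)
})

test_that("connected components match the flood-fill oracle on random fields", {
  set.seed(6)
  for (i in 1:5) {
    x <- array(runif(10 * 10 * 5) < 0.25, c(10, 10, 5))
    got <- label_components(x)
    ora <- oracle_flood_fill(x)
    expect_identical(got$n, max(ora))
    # same partition: component ids agree up to relabelling
    if (got$n > 0) {
      pairs <- unique(cbind(got$labels, ora[got$index]))
      expect_identical(nrow(pairs), got$n)
      expect_identical(length(unique(pairs[, 2])), got$n)
    }
  }
})

test_that("reference subjects label none of their own voxels at tau = 0", {
  sch <- make_scheme(n_directions = 6)
  fits <- lapply(1:3, function(s) {
    ph <- build_phantom(small_spec(seed = s, include_tumor = FALSE))
    list(ph = ph, fit = fit_volume(simulate_dwi(ph, sch, snr = Inf),
                                   ph$brain_mask, sigma = 0))
  })
  hs <- lapply(fits, function(f)
    joint_histogram(f$fit$md, f$fit$mk, f$ph$brain_mask))
  occ <- build_reference_occupancy(hs, tau = 0, dilate = 0)
  reg <- derive_signature_region(occ)
  for (f in fits) {
    lab <- label_voxels(f$fit$md, f$fit$mk, f$ph$brain_mask, reg,
                        min_cluster = 0)
    expect_identical(sum(lab$values), 0L)
  }
})

test_that("raising tau enlarges the region and never shrinks the labels", {
  sch <- make_scheme(n_directions = 6)
  ph <- build_phantom(small_spec(seed = 21, include_tumor = FALSE, snr = 40))
  fit <- fit_volume(simulate_dwi(ph, sch), ph$brain_mask, sigma = 1.25)
  h <- joint_histogram(fit$md, fit$mk, ph$brain_mask)
  case <- build_phantom(small_spec(seed = 22))
  cfit <- fit_volume(simulate_dwi(case, sch, snr = Inf), case$brain_mask,
                     sigma = 0)
  prev <- NULL
  for (tau in c(0, 1e-4, 1e-3)) {
    occ <- build_reference_occupancy(list(h), tau = tau, dilate = 0)
    reg <- derive_signature_region(occ)
    lab <- label_voxels(cfit$md, cfit$mk, case$brain_mask, reg,
                        min_cluster = 0)
    if (!is.null(prev)) {
      expect_true(all(reg$region[prev$region]))
      expect_true(all(lab$values[prev$lab]))
    }
    prev <- list(region = reg$region, lab = lab$values)
  }
})

test_that("a manual MK-MD gate labels exactly the voxels inside it", {
  mp <- make_map_pair(c(1.3, 0.8, 2.0, 1.25), c(0.45, 1.0, 0.3, 0.5),
                      shape = c(4, 1, 1))
  gate <- manual_gate_region(c(1.2, 1.4), c(0.4, 0.6))
  lab <- label_voxels(mp$md, mp$mk, mp$mask, gate, min_cluster = 0)
  expect_identical(as.vector(lab$values), c(TRUE, FALSE, FALSE, TRUE))
})
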