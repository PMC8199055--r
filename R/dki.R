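#' Predict the diffusion-kurtosis signal
#'
#' Closed-form kurtosis signal representation
#' `S(b) = s0 exp(-b d + b^2 d^2 k / 6)`, the second-order cumulant expansion
#' of the diffusion-induced signal decay in which the apparent kurtosis k
#' quantifies the deviation from monoexponential (Gaussian) decay.  Units
#' are handled so that b = 1000 s/mm^2 with d = 1.0 x 10^-3 mm^2/s
#' contributes -1 to the exponent.  The representation decays only up to
#' b = 3/(d k); a warning is emitted if it is evaluated beyond that point.
#'
#' @param s0 signal at b = 0 (a.u.), > 0.
#' @param d apparent diffusivity, 10^-3 mm^2/s, > 0.
#' @param k apparent kurtosis coefficient (dimensionless), >= 0.
#' @param b b-value(s), s/mm^2, >= 0.
#' @return predicted signal, a.u. (vectorised over `b`).
#' @examples
#' predict_signal(1, 1.0, 1, 1000)  # exp(-5/6)
#' @export
predict_signal <- function(s0, d, k, b) {
  stopifnot(s0 > 0, d > 0, k >= 0, all(b >= 0))
  if (any(k > 0 & b * 1e-3 > 3 / (d * k)))
    warning("b exceeds 3/(d*k): signal representation is non-monotone there",
            call. = FALSE)
  s0 * exp(kurtosis_exponent(b, d, k))
}

# Per-direction log-linear kurtosis fit, vectorised over voxels.
#
# For each encoding direction the model ln S = ln s0 - b d + b^2 w (with
# w = d^2 k / 6, b in 1e3 s/mm^2 units) is solved by (optionally weighted)
# least squares over that direction's b-series including the shared b = 0
# sample.  The 3x3 normal equations are solved in closed form (Cramer's
# rule) on per-voxel moment sums, so the same code path serves the
# unweighted and the signal-squared-weighted estimator.
#
# logS: n_voxel x n_volume matrix of log signals; weights NULL or a matrix
# of the same shape.  Returns per-direction d_app/k_app (n_voxel x n_dir)
# plus clamp counters.
dki_fit_core <- function(logS, scheme, k_max = 3, d_max = 5,
                         weights = NULL, d_min = 1e-6) {
  groups <- scheme_direction_groups(scheme)
  n_dir <- length(groups$directions)
  n <- nrow(logS)
  d_app <- k_app <- s0_app <- matrix(NA_real_, n, n_dir)
  n_clamp_d <- n_clamp_k <- 0L

  for (g in seq_len(n_dir)) {
    vols <- c(groups$b0, groups$directions[[g]])
    b <- scheme$bvals[vols] * 1e-3
    y <- logS[, vols, drop = FALSE]
    w <- if (is.null(weights)) matrix(1, n, length(vols))
         else weights[, vols, drop = FALSE]

    bp <- outer(b, 0:4, `^`)                       # moments of the design
    m <- w %*% bp                                  # n x 5: sum w b^p
    wy <- w * y
    v <- wy %*% bp[, 1:3]                          # n x 3: sum w y b^p

    # symmetric normal matrix for basis (1, -b, b^2)
    a11 <- m[, 1]; a12 <- -m[, 2]; a13 <- m[, 3]
    a22 <- m[, 3]; a23 <- -m[, 4]; a33 <- m[, 5]
    b1 <- v[, 1]; b2 <- -v[, 2]; b3 <- v[, 3]

    det0 <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
            a13 * (a12 * a23 - a22 * a13)
    det1 <- b1 * (a22 * a33 - a23^2) - b2 * (a12 * a33 - a13 * a23) +
            b3 * (a12 * a23 - a13 * a22)
    det2 <- a11 * (b2 * a33 - a23 * b3) - a12 * (b1 * a33 - a13 * b3) +
            a13 * (b1 * a23 - a13 * b2)
    det3 <- a11 * (a22 * b3 - b2 * a23) - a12 * (a12 * b3 - b1 * a23) +
            a13 * (a12 * b2 - a22 * b1)

    lns0 <- det1 / det0
    d_raw <- det2 / det0
    w_raw <- det3 / det0

    n_clamp_d <- n_clamp_d + sum(d_raw < d_min | d_raw > d_max)
    d_c <- pmin(pmax(d_raw, d_min), d_max)
    k_raw <- 6 * w_raw / d_c^2
    n_clamp_k <- n_clamp_k + sum(k_raw < 0 | k_raw > k_max)
    k_c <- pmin(pmax(k_raw, 0), k_max)

    s0_app[, g] <- exp(lns0)
    d_app[, g] <- d_c
    k_app[, g] <- k_c
  }
  list(d_app = d_app, k_app = k_app, s0_app = s0_app,
       n_clamp_d = n_clamp_d, n_clamp_k = n_clamp_k)
}

#' Fit the kurtosis representation in a single voxel
#'
#' Per encoding direction, solves `ln S = ln s0 - b d + b^2 w` by least
#' squares over that direction's b-series (the b = 0 sample is shared by all
#' directions), recovers the apparent kurtosis `k = 6 w / d^2`, clamps d to
#' `(0, d_max]` and k to `[0, k_max]`, and averages over directions: MD is
#' the mean apparent diffusivity, MK the mean apparent kurtosis.
#'
#' @param signals per-volume signal vector matching `scheme`.
#' @param scheme a [make_scheme()] acquisition.
#' @param k_max,d_max physiological clamp bounds (dimensionless;
#'   10^-3 mm^2/s).
#' @param weighted use signal-squared weights in the log-domain fit
#'   (compensates the log transform's noise amplification at low signal).
#' @return an object of class `voxel_fit`: `s0`, per-direction `d_app` and
#'   `k_app`, their means `md` and `mk`, `valid` flag and failure `code`
#'   (`"ok"`, `"nonpositive_b0"`, `"nonpositive_signal"`,
#'   `"insufficient_data"`).
#' @export
fit_voxel <- function(signals, scheme, k_max = 3, d_max = 5,
                      weighted = FALSE) {
  stopifnot(inherits(scheme, "dki_scheme"),
            length(signals) == n_volumes(scheme))
  invalid <- function(code) {
    structure(list(s0 = NA_real_, d_app = NULL, k_app = NULL,
                   md = NA_real_, mk = NA_real_, valid = FALSE, code = code),
              class = "voxel_fit")
  }
  b0 <- scheme$bvals == 0
  if (any(signals[b0] <= 0)) return(invalid("nonpositive_b0"))
  if (any(signals <= 0)) return(invalid("nonpositive_signal"))
  groups <- tryCatch(scheme_direction_groups(scheme), error = function(e) e)
  if (inherits(groups, "error")) return(invalid("insufficient_data"))

  logS <- matrix(log(signals), nrow = 1)
  wts <- if (weighted) matrix(signals^2, nrow = 1) else NULL
  fit <- dki_fit_core(logS, scheme, k_max = k_max, d_max = d_max,
                      weights = wts)
  structure(list(s0 = mean(fit$s0_app[1, ]),
                 d_app = fit$d_app[1, ], k_app = fit$k_app[1, ],
                 md = mean(fit$d_app[1, ]), mk = mean(fit$k_app[1, ]),
                 valid = TRUE, code = "ok"),
            class = "voxel_fit")
}

#' @export
print.voxel_fit <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<voxel_fit> MD = %.4f, MK = %.4f (%d directions)\n",
                x$md, x$mk, length(x$d_app)))
  else
    cat("<voxel_fit> invalid:", x$code, "\n")
  invisible(x)
}

#' Gaussian pre-smoothing of a DWI series
#'
#' Smooths every volume with an isotropic (in world mm) Gaussian kernel.
#' `sigma` is given in in-plane voxels; the per-axis kernel width is scaled
#' by the voxel size so through-plane smoothing matches the in-plane extent
#' in millimetres.  Kernels are renormalised at the array edges, so constant
#' volumes are preserved exactly.  `sigma = 0` returns the input unchanged.
#'
#' @param dwi a `dwi_volume`.
#' @param sigma kernel standard deviation in in-plane voxels, >= 0.
#' @return a smoothed `dwi_volume`.
#' @export
smooth_dwi <- function(dwi, sigma) {
  stopifnot(inherits(dwi, "dwi_volume"), is.numeric(sigma), sigma >= 0)
  if (sigma == 0) return(dwi)
  sigma_mm <- sigma * dwi$grid$voxel_size[1]
  sigma_vox <- sigma_mm / dwi$grid$voxel_size
  kernels <- lapply(seq_len(3), function(ax)
    gaussian_band_matrix(dwi$grid$shape[ax], sigma_vox[ax]))
  out <- dwi$signal
  for (v in seq_len(dim(out)[4])) {
    vol <- out[, , , v]
    for (ax in 1:3)
      if (!is.null(kernels[[ax]])) vol <- apply_axis(vol, kernels[[ax]], ax)
    out[, , , v] <- vol
  }
  new_dwi_volume(out, dwi$grid, dwi$scheme, dwi$sigma)
}

# Dense n x n 1D Gaussian convolution matrix, truncated at 4 sigma, with
# rows renormalised (edge renormalisation preserves constants exactly).
gaussian_band_matrix <- function(n, sigma_vox) {
  if (sigma_vox < 1e-8) return(NULL)
  radius <- max(1L, ceiling(4 * sigma_vox))
  offs <- -radius:radius
  g <- exp(-offs^2 / (2 * sigma_vox^2))
  K <- matrix(0, n, n)
  for (t in seq_along(offs)) {
    j <- seq_len(n) + offs[t]
    ok <- j >= 1 & j <= n
    K[cbind(which(ok), j[ok])] <- K[cbind(which(ok), j[ok])] + g[t]
  }
  K / rowSums(K)
}

# Multiply a 3D array by a matrix along one axis.
apply_axis <- function(arr, K, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- K %*% matrix(a, nrow = d[axis])
  dim(m) <- d[perm]
  aperm(m, order(perm))
}

#' Fit MD and MK parametric maps over a volume
#'
#' Applies optional Gaussian pre-smoothing, then the per-direction
#' log-linear kurtosis fit at every voxel of the brain mask.  Voxels outside
#' the mask, or with nonpositive signal in any volume, carry the invalid
#' marker (`NA`).
#'
#' @param dwi a `dwi_volume`.
#' @param brain_mask a [seg_mask()] on the DWI grid.
#' @param sigma pre-smoothing kernel width in in-plane voxels (see
#'   [smooth_dwi()]); default 1.25.
#' @param k_max,d_max clamp bounds as in [fit_voxel()].
#' @param weighted signal-squared weighting flag.
#' @return an object of class `dki_fit`: parametric maps `md` and `mk` and a
#'   `stats` list (voxel counts fitted / invalid by failure code, clamp
#'   counts).
#' @export
fit_volume <- function(dwi, brain_mask, sigma = 1.25, k_max = 3, d_max = 5,
                       weighted = FALSE) {
  stopifnot(inherits(dwi, "dwi_volume"), inherits(brain_mask, "seg_mask"))
  if (!grids_identical(dwi$grid, brain_mask$grid))
    stop("brain mask is not on the DWI grid", call. = FALSE)

  dwi <- smooth_dwi(dwi, sigma)
  shape <- dwi$grid$shape
  n_vol <- n_volumes(dwi$scheme)
  sigmat <- matrix(dwi$signal, prod(shape), n_vol)

  idx <- which(brain_mask$values)
  md_vals <- mk_vals <- rep(NA_real_, prod(shape))
  stats <- list(n_masked = length(idx), n_fitted = 0L,
                n_nonpositive_b0 = 0L, n_nonpositive_signal = 0L,
                n_clamp_d = 0L, n_clamp_k = 0L)
  if (length(idx)) {
    s <- sigmat[idx, , drop = FALSE]
    b0 <- dwi$scheme$bvals == 0
    bad_b0 <- rowSums(s[, b0, drop = FALSE] <= 0) > 0
    bad_any <- rowSums(s <= 0) > 0
    stats$n_nonpositive_b0 <- sum(bad_b0)
    stats$n_nonpositive_signal <- sum(bad_any & !bad_b0)
    ok <- !bad_any
    stats$n_fitted <- sum(ok)
    if (any(ok)) {
      logS <- log(s[ok, , drop = FALSE])
      wts <- if (weighted) s[ok, , drop = FALSE]^2 else NULL
      fit <- dki_fit_core(logS, dwi$scheme, k_max = k_max, d_max = d_max,
                          weights = wts)
      md_vals[idx[ok]] <- rowMeans(fit$d_app)
      mk_vals[idx[ok]] <- rowMeans(fit$k_app)
      stats$n_clamp_d <- fit$n_clamp_d
      stats$n_clamp_k <- fit$n_clamp_k
    }
  }
  structure(list(
    md = parametric_map(array(md_vals, shape), "MD", dwi$grid),
    mk = parametric_map(array(mk_vals, shape), "MK", dwi$grid),
    stats = stats
  ), class = "dki_fit")
}

#' @export
print.dki_fit <- function(x, ...) {
  cat("<dki_fit> ", x$stats$n_fitted, " voxels fitted of ",
      x$stats$n_masked, " masked (",
      x$stats$n_nonpositive_b0 + x$stats$n_nonpositive_signal,
      " invalid)\n", sep = "")
  invisible(x)
}
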