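# The kurtosis signal representation underlying both the simulator and the
# fitter: S(b) = S0 exp(-b D + b^2 D^2 K / 6), with b in s/mm^2 and D in
# 10^-3 mm^2/s, so b is rescaled by 1e-3 to make the exponent dimensionless
# (b = 1000 with D = 1.0 contributes -1).
kurtosis_exponent <- function(b, d, k) {
  bm <- b * 1e-3
  -bm * d + bm^2 * d^2 * k / 6
}

#' Forward-simulate multi-shell DWI from a phantom
#'
#' Evaluates the diffusion-kurtosis signal representation
#' `S = S0 exp(-b MD + b^2 MD^2 MK / 6)` per voxel and volume (the phantom is
#' isotropic, so every encoding direction sees the same MD and MK) and
#' applies Rician noise: independent Gaussian noise of standard deviation
#' `sigma = S0_ref / snr` on two quadrature channels, followed by the
#' magnitude.  `S0_ref` is the mean S0 over brain voxels.  The representation
#' is only a decaying function of b up to b = 3/(MD MK); the simulator
#' verifies that the largest b-value respects this bound at every brain voxel
#' and refuses to extrapolate beyond it.
#'
#' @param truth a [build_phantom()] result.
#' @param scheme a [make_scheme()] acquisition.
#' @param snr b = 0 signal-to-noise ratio; `Inf` for noiseless.  Defaults to
#'   the phantom spec's value.
#' @param seed RNG seed for the noise (defaults to the phantom's seed).
#' @return an object of class `dwi_volume`: 4D `signal` array, `grid`,
#'   `scheme`, and the noise `sigma` used.
#' @export
simulate_dwi <- function(truth, scheme, snr = truth$spec$snr,
                         seed = truth$spec$seed) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(scheme, "dki_scheme"))
  if (!is.numeric(snr) || length(snr) != 1L || is.na(snr) || snr <= 0)
    stop("snr must be positive (Inf allowed)", call. = FALSE)

  brain <- truth$brain_mask$values
  md <- truth$md_truth; mk <- truth$mk_truth; s0 <- truth$s0_truth
  # validity range of the kurtosis representation: b <= 3/(MD MK)
  bmax <- max(scheme$bvals) * 1e-3
  prod_dk <- md[brain] * mk[brain]
  if (any(prod_dk > 0 & bmax > 3 / prod_dk))
    stop(sprintf(paste("max b-value %g s/mm^2 exceeds the kurtosis",
                       "representation's validity range 3/(MD*MK) for some",
                       "brain voxels"), max(scheme$bvals)), call. = FALSE)

  shape <- truth$grid$shape
  n_vox <- prod(shape)
  n_vol <- n_volumes(scheme)
  signal <- matrix(0, n_vox, n_vol)
  # isotropic phantom: the signal depends on the volume only through b
  for (b in unique(scheme$bvals)) {
    cols <- which(scheme$bvals == b)
    s <- as.vector(s0) * exp(kurtosis_exponent(b, as.vector(md),
                                               as.vector(mk)))
    signal[, cols] <- s
  }

  sigma <- 0
  if (is.finite(snr)) {
    sigma <- mean(s0[brain]) / snr
    set.seed(seed)
    re <- signal + stats::rnorm(length(signal), 0, sigma)
    im <- stats::rnorm(length(signal), 0, sigma)
    signal <- sqrt(re * re + im * im)
  }
  dim(signal) <- c(shape, n_vol)
  structure(list(signal = signal, grid = truth$grid, scheme = scheme,
                 sigma = sigma),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  cat("<dwi_volume> ", format(x$grid), " x ", n_volumes(x$scheme),
      " volumes\n", sep = "")
  invisible(x)
}

new_dwi_volume <- function(signal, grid, scheme, sigma = NA_real_) {
  stopifnot(length(dim(signal)) == 4L,
            dim(signal)[4] == n_volumes(scheme),
            identical(dim(signal)[1:3], as.integer(grid$shape)))
  structure(list(signal = signal, grid = grid, scheme = scheme,
                 sigma = sigma),
            class = "dwi_volume")
}
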