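sch <- make_scheme(n_directions = 8)

test_that("predict_signal evaluates the closed form exactly", {
  expect_identical(predict_signal(1, 0.8, 1.2, 0), 1.0)
  expect_equal(predict_signal(1, 1.0, 0, 1000), exp(-1))
  expect_equal(predict_signal(1, 1.0, 1, 1000), exp(-5 / 6))
  expect_equal(predict_signal(100, 1.0, 1, 1000), 43.4598209, tolerance = 1e-7)
  expect_warning(predict_signal(1, 2.0, 1.5, 2500), "non-monotone")
  expect_error(predict_signal(-1, 1, 1, 1000))
  expect_error(predict_signal(1, 0, 1, 1000))
})

test_that("noiseless fit recovers forward-model parameters to 1e-9", {
  sig <- predict_signal(100, 0.8, 1.2, sch$bvals)
  fit <- fit_voxel(sig, sch)
  expect_true(fit$valid)
  expect_lt(abs(fit$md - 0.8) / 0.8, 1e-9)
  expect_lt(abs(fit$mk - 1.2) / 1.2, 1e-9)
  # k = 0 ground truth: monoexponential decay fitted as such
  fit0 <- fit_voxel(predict_signal(100, 1.1, 0, sch$bvals), sch)
  expect_lt(abs(fit0$mk), 1e-9)
})

test_that("parameter roundtrip holds across randomized parameter space", {
  set.seed(42)
  for (i in 1:50) {
    s0 <- runif(1, 10, 500)
    d <- runif(1, 0.2, 3.0)
    k_lim <- min(2.5, 3 / (2.5 * d) * 0.95)   # keep max b inside validity
    k <- runif(1, 0.05, k_lim)
    fit <- fit_voxel(predict_signal(s0, d, k, sch$bvals), sch)
    expect_lt(abs(fit$md - d) / d, 1e-9)
    expect_lt(abs(fit$mk - k) / k, 1e-9)
    expect_lt(abs(fit$s0 - s0) / s0, 1e-9)
  }
})

test_that("MD and MK are exactly the means of per-direction estimates", {
  set.seed(7)
  sig <- predict_signal(100, 1.0, 0.8, sch$bvals) *
    exp(rnorm(length(sch$bvals), 0, 0.05))
  fit <- fit_voxel(sig, sch)
  expect_identical(fit$md, mean(fit$d_app))
  expect_identical(fit$mk, mean(fit$k_app))
  expect_true(all(fit$k_app >= 0 & fit$k_app <= 3))
})

test_that("fit agrees with an independent lm()-based solver", {
  set.seed(13)
  for (i in 1:5) {
    sig <- predict_signal(120, 0.9, 1.1, sch$bvals) *
      exp(rnorm(length(sch$bvals), 0, 0.1))
    fit <- fit_voxel(sig, sch)
    ora <- oracle_lm_fit(sig, sch)
    expect_equal(fit$md, ora$md, tolerance = 1e-8)
    expect_equal(fit$mk, ora$mk, tolerance = 1e-8)
    expect_equal(fit$d_app, ora$d_app, tolerance = 1e-8)
  }
})

test_that("weighted and unweighted estimators agree on noiseless data", {
  sig <- predict_signal(80, 1.4, 0.6, sch$bvals)
  fu <- fit_voxel(sig, sch, weighted = FALSE)
  fw <- fit_voxel(sig, sch, weighted = TRUE)
  expect_equal(fu$md, fw$md, tolerance = 1e-9)
  expect_equal(fu$mk, fw$mk, tolerance = 1e-9)
})

test_that("degenerate signals are flagged, not fitted", {
  sig <- predict_signal(100, 0.8, 1.2, sch$bvals)
  sig[length(sig)] <- 0           # a zero at b = 2500
  fit <- fit_voxel(sig, sch)
  expect_false(fit$valid)
  expect_identical(fit$code, "nonpositive_signal")
  sig2 <- predict_signal(100, 0.8, 1.2, sch$bvals)
  sig2[1] <- -1                   # nonpositive b = 0
  expect_identical(fit_voxel(sig2, sch)$code, "nonpositive_b0")
})

test_that("raising k_max never lowers a fitted kurtosis", {
  set.seed(99)
  for (i in 1:10) {
    sig <- predict_signal(100, 0.7, 1.5, sch$bvals) *
      exp(rnorm(length(sch$bvals), 0, 0.2))
    k_lo <- fit_voxel(sig, sch, k_max = 1)$k_app
    k_hi <- fit_voxel(sig, sch, k_max = 3)$k_app
    expect_true(all(k_hi >= k_lo - 1e-12))
  }
})

test_that("smoothing preserves constants and total mass, sigma = 0 is identity", {
  ph <- build_phantom(small_spec(seed = 1))
  sch3 <- make_scheme(c(0, 500, 1000, 1500), 6)
  dwi <- simulate_dwi(ph, sch3, snr = Inf)
  expect_identical(smooth_dwi(dwi, 0)$signal, dwi$signal)

  shape <- c(16, 16, 8)
  grid <- vox_grid(shape, c(2, 2, 5))
  const <- kurtosig:::new_dwi_volume(array(7, c(shape, length(sch3$bvals))),
                                     grid, sch3)
  sm <- smooth_dwi(const, 2)
  expect_lt(max(abs(sm$signal - 7)), 1e-12)

  imp <- array(0, c(shape, length(sch3$bvals)))
  imp[8, 8, 4, ] <- 1
  impulse <- kurtosig:::new_dwi_volume(imp, grid, sch3)
  sm1 <- smooth_dwi(impulse, 1)
  expect_lt(abs(sum(sm1$signal[, , , 1]) - 1), 1e-6)
  expect_gt(max(sm1$signal[, , , 1]), 0)
})

test_that("smoothing lowers noise variance in homogeneous tissue", {
  ph <- build_phantom(small_spec(seed = 6, snr = 40))
  sch3 <- make_scheme(c(0, 500, 1000, 1500, 2000, 2500), 6)
  dwi <- simulate_dwi(ph, sch3, snr = 40)
  wm_core <- ph$label_volume == 1L
  b0 <- which(sch3$bvals == 0)
  v_raw <- stats::var(dwi$signal[, , , b0][wm_core])
  v_sm <- stats::var(smooth_dwi(dwi, 1)$signal[, , , b0][wm_core])
  expect_lt(v_sm / v_raw, 1)
})

test_that("fit_volume reproduces noiseless truth and flags the rest", {
  ph <- build_phantom(small_spec(seed = 2))
  dwi <- simulate_dwi(ph, sch, snr = Inf)
  fit <- fit_volume(dwi, ph$brain_mask, sigma = 0)
  b <- ph$brain_mask$values
  expect_identical(fit$stats$n_fitted, sum(b))
  expect_lt(max(abs(fit$md$values[b] - ph$md_truth[b]) / ph$md_truth[b]),
            1e-6)
  expect_lt(max(abs(fit$mk$values[b] - ph$mk_truth[b])), 1e-6)
  expect_true(all(is.na(fit$md$values[!b])))

  empty <- seg_mask(array(FALSE, ph$grid$shape), ph$grid)
  fit0 <- fit_volume(dwi, empty, sigma = 0)
  expect_identical(fit0$stats$n_fitted, 0L)
  expect_true(all(is.na(fit0$md$values)))

  other <- seg_mask(array(TRUE, c(8, 8, 4)), vox_grid(c(8, 8, 4), c(2, 2, 5)))
  expect_error(fit_volume(dwi, other, sigma = 0), "grid")
})
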