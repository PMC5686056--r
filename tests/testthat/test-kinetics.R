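test_that("region curves reconstruct exactly on factorizable data", {
  fx <- exact_factorization_fixture()
  r <- run_nmf(fx$cm, 3)
  mask <- array(FALSE, r$dim3)
  mask[1:40] <- TRUE   # inside the first voxel group
  crv <- reconstruct_curve(r, mask_volume(mask, "ROI"))
  truth <- colMeans((fx$W0 %*% fx$S0)[1:40, ])
  expect_equal(crv$values, truth, tolerance = 1e-6)
  # single-voxel mask reconstructs that voxel's row
  m1 <- array(FALSE, r$dim3); m1[3] <- TRUE
  crv1 <- reconstruct_curve(r, mask_volume(m1, "ROI"))
  expect_equal(crv1$values, as.numeric(r$W[3, ] %*% r$S))
  # identical-weight voxels: mean equals any single reconstruction
  r2 <- r; r2$W[1:5, ] <- rep(r$W[1, ], each = 5)
  m5 <- array(FALSE, r$dim3); m5[1:5] <- TRUE
  expect_equal(reconstruct_curve(r2, mask_volume(m5, "ROI"))$values,
               as.numeric(r2$W[1, ] %*% r2$S))
  expect_error(reconstruct_curve(r, mask_volume(array(FALSE, r$dim3), "ROI")),
               "empty")
})

test_that("raw region means are baseline-corrected without clipping", {
  arr <- array(0, c(2, 1, 1, 4))
  arr[1, 1, 1, ] <- c(10, 10, 20, 30)
  arr[2, 1, 1, ] <- c(30, 30, 20, 10)   # mirror curve about the baselines
  s <- quick_series(arr)
  m <- mask_volume(array(TRUE, c(2, 1, 1)), "GM")
  crv <- mean_raw_curve(s, m)
  expect_equal(crv$values, c(0, 0, 0, 0))
  # constant region is exactly zero
  arr2 <- array(7, c(2, 2, 1, 4))
  expect_equal(mean_raw_curve(quick_series(arr2),
                              mask_volume(array(TRUE, c(2, 2, 1)), "GM"))$values,
               rep(0, 4))
  # noiseless phantom muscle equals the muscle kinetic curve minus baseline
  ph <- make_phantom(phantom_config(partial_volume = FALSE))
  mus <- kinetics_presets()$muscle
  crv3 <- mean_raw_curve(ph$series, ph$truth$gm, "muscle_mean")
  expected <- kinetic_curve(mus, ph$series$grid) - mus$s0
  expected[1:2] <- 0
  expect_equal(crv3$values, expected, tolerance = 1e-10)
})

test_that("measured-curve areas integrate piecewise-linearly with interpolated ends", {
  tg <- time_grid()
  expect_equal(curve_auc(signal_curve(rep(1, 12), tg), 60, 120), 60)
  ramp <- signal_curve(tg$times / 330, tg)
  expect_equal(curve_auc(ramp, 240, 330), (330^2 - 240^2) / (2 * 330))
  # windows off the frame grid agree with a dense-grid oracle
  set.seed(3)
  v <- cumsum(runif(12))
  crv <- signal_curve(v, tg)
  dense_t <- seq(0, 330, by = 0.01)
  dense_v <- approx(tg$times, v, xout = dense_t)$y
  for (w in list(c(45, 200), c(75, 285), c(60, 120))) {
    oracle <- sum(diff(dense_t) * (head(dense_v, -1) + tail(dense_v, -1)) / 2 *
                    (head(dense_t, -1) >= w[1] - 1e-12 & tail(dense_t, -1) <= w[2] + 1e-12))
    expect_equal(curve_auc(crv, w[1], w[2]), oracle, tolerance = 1e-6)
  }
  expect_error(curve_auc(crv, 120, 60), "t1")
  expect_error(curve_auc(crv, 0, 400), "outside")
})

test_that("the bi-exponential fit recovers noiseless generative parameters", {
  tg <- time_grid()
  p <- kinetics_presets()$lesion_g34
  v <- kinetic_curve(p, tg) - p$s0; v[1:2] <- 0
  fit <- fit_biexp(signal_curve(v, tg))
  expect_true(fit$valid)
  expect_lt(abs(fit$tau - p$tau) / p$tau, 0.02)
  expect_lt(abs(fit$sm - (p$sm - p$s0)) / (p$sm - p$s0), 0.02)
  expect_lt(fit$s0, 0.02 * (p$sm - p$s0))
})

test_that("the fit is scale-equivariant and flat on plateau curves", {
  tg <- time_grid()
  p <- kinetics_presets()$lesion_g43
  v <- kinetic_curve(p, tg) - p$s0; v[1:2] <- 0
  f1 <- fit_biexp(signal_curve(v, tg))
  f2 <- fit_biexp(signal_curve(2 * v, tg))
  expect_equal(f2$sm / f1$sm, 2, tolerance = 1e-3)
  expect_equal(f2$wo_biexp / f1$wo_biexp, 2, tolerance = 1e-2)
  expect_equal(f2$tau, f1$tau, tolerance = 1e-2 * f1$tau)
  expect_equal(f2$k1, f1$k1, tolerance = 1e-3 * f1$k1)
  # monotone plateau (no washout) has essentially zero model washout
  pl <- tissue_kinetics(s0 = 0, A = 100, k1 = 0.05, k2 = 0, t0 = 30)
  fpl <- fit_biexp(signal_curve(kinetic_curve(pl, tg), tg))
  expect_lt(abs(fpl$wo_biexp), 1e-3 * fpl$sm)
  # non-enhancing curve flags invalid
  expect_false(fit_biexp(signal_curve(rep(5, 12), tg))$valid)
})

test_that("noisy time-to-peak recovery stays within tolerance at SNR 20", {
  tg <- time_grid()
  p <- kinetics_presets()$lesion_g34
  v <- kinetic_curve(p, tg) - p$s0; v[1:2] <- 0
  sigma <- (p$sm - p$s0) / 20
  errs <- vapply(1:40, function(sd) {
    set.seed(sd)
    f <- fit_biexp(signal_curve(pmax(v + rnorm(12, 0, sigma), 0), tg))
    abs(f$tau - p$tau) / p$tau
  }, numeric(1))
  expect_lte(median(errs), 0.10)
})

test_that("fitted-curve areas match the analytic exponential integral", {
  tg <- time_grid()
  p <- kinetics_presets()$lesion_g6
  v <- kinetic_curve(p, tg) - p$s0; v[1:2] <- 0
  fit <- fit_biexp(signal_curve(v, tg))
  analytic <- function(f, t1, t2) {
    d1 <- t1 - f$t0; d2 <- t2 - f$t0
    f$s0 * (t2 - t1) +
      f$A * ((exp(-f$k2 * d1) - exp(-f$k2 * d2)) / f$k2 -
             (exp(-f$k1 * d1) - exp(-f$k1 * d2)) / f$k1)
  }
  expect_equal(aufc(fit, 60, 120), analytic(fit, 60, 120),
               tolerance = 1e-4)
  expect_equal(aufc(fit, 240, 330), analytic(fit, 240, 330),
               tolerance = 1e-4)
  # additivity over abutting windows
  expect_equal(aufc(fit, 60, 120) + aufc(fit, 120, 240) + aufc(fit, 240, 330),
               aufc(fit, 60, 330), tolerance = 1e-9)
  # flat model integrates to the rectangle
  flat <- structure(list(s0 = 3, A = 0, t0 = 0, k1 = 0.05, k2 = 0.001,
                         sm = 3, tau = 1, wo_biexp = 0, rmse = 0,
                         valid = TRUE, grid = tg), class = "biexp_params")
  expect_equal(aufc(flat, 60, 120), 180)
})

test_that("late linear fits are exact on lines and unbiased under noise", {
  tg <- time_grid()
  v <- rep(0, 12)
  v[tg$times >= 270] <- c(10, 9, 8)
  ll <- fit_late_linear(signal_curve(v, tg))
  expect_equal(ll$wo_linear, -1 / 30)
  expect_equal(ll$n_frames, 3)
  vflat <- rep(4, 12)
  expect_equal(fit_late_linear(signal_curve(vflat, tg))$wo_linear, 0)
  # unbiasedness: mean estimate over many draws approaches the true slope
  set.seed(9)
  true_slope <- -0.02
  ests <- replicate(1000, {
    vv <- rep(0, 12)
    vv[10:12] <- 5 + true_slope * (c(270, 300, 330) - 270) + rnorm(3, 0, 0.5)
    fit_late_linear(signal_curve(vv, tg))$wo_linear
  })
  se <- 0.5 / sqrt(1000) * sqrt(1 / sum((c(270, 300, 330) - 300)^2))
  expect_lt(abs(mean(ests) - true_slope), 4 * se)
  expect_error(fit_late_linear(signal_curve(v, tg), window = c(320, 330)), "2 frames")
})

test_that("feature sets self-normalize to one and follow the definitions", {
  tg <- time_grid()
  p <- kinetics_presets()$lesion_g34
  v <- kinetic_curve(p, tg) - p$s0; v[1:2] <- 0
  crv <- signal_curve(v, tg)
  fs <- feature_set(crv, crv)
  expect_true(all(fs$table$valid))
  expect_equal(fs$table$ratio, rep(1, 6), tolerance = 1e-9)
  # wash-in definition: (sm - s0) / tau
  fit <- fit_biexp(crv)
  expect_equal(get_feature(feature_set(crv), "wash_in"),
               (fit$sm - fit$s0) / fit$tau)
  # wash-out = minus the late linear slope
  expect_equal(get_feature(feature_set(crv), "wash_out"),
               -fit_late_linear(crv)$wo_linear)
  expect_error(get_feature(feature_set(crv), "early_aufc_ratio"), "muscle")
})

test_that("non-enhancing muscle invalidates ratios but keeps raw features", {
  tg <- time_grid()
  p <- kinetics_presets()$lesion_g34
  v <- kinetic_curve(p, tg) - p$s0; v[1:2] <- 0
  flat_muscle <- signal_curve(rep(0, 12), tg, "muscle_mean")
  fs <- feature_set(signal_curve(v, tg), flat_muscle)
  expect_false(any(fs$table$valid))
  expect_true(all(is.na(fs$table$ratio)))
  expect_true(all(is.finite(fs$table$raw[c(1, 2, 6)])))
})

test_that("all six normalized features increase strictly with lesion grade", {
  tg <- time_grid()
  kin <- kinetics_presets()
  mv <- kinetic_curve(kin$muscle, tg) - kin$muscle$s0; mv[1:2] <- 0
  muscle <- signal_curve(mv, tg, "muscle_mean")
  ratios <- sapply(c("lesion_g6", "lesion_g34", "lesion_g43", "lesion_g8"),
                   function(g) {
    v <- kinetic_curve(kin[[g]], tg) - kin[[g]]$s0; v[1:2] <- 0
    fs <- feature_set(signal_curve(v, tg), muscle)
    expect_true(all(fs$table$valid))
    fs$table$ratio
  })
  expect_true(all(apply(ratios, 1, function(r) all(diff(r) > 0))))
})

test_that("ratio features are invariant to global intensity scaling", {
  tg <- time_grid()
  kin <- kinetics_presets()
  v <- kinetic_curve(kin$lesion_g43, tg) - 100; v[1:2] <- 0
  mv <- kinetic_curve(kin$muscle, tg) - 100; mv[1:2] <- 0
  f1 <- feature_set(signal_curve(v, tg), signal_curve(mv, tg, "muscle_mean"))
  f2 <- feature_set(signal_curve(3 * v, tg),
                    signal_curve(3 * mv, tg, "muscle_mean"))
  expect_equal(f2$table$ratio, f1$table$ratio, tolerance = 1e-6)
})
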