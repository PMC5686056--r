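#' Baseline-corrected signal-time curve
#'
#' @param values Numeric vector, one value per frame.
#' @param grid A [time_grid()].
#' @param source Provenance label: `"roi_reconstructed"`, `"roi_raw_mean"`,
#'   `"muscle_mean"` or `"nat"`.
#' @return An object of class `signal_curve`.
#' @export
signal_curve <- function(values, grid = time_grid(),
                         source = c("roi_reconstructed", "roi_raw_mean",
                                    "muscle_mean", "nat")) {
  source <- match.arg(source)
  values <- as.numeric(values)
  if (length(values) != length(grid$times)) stop("curve length must match the grid")
  if (!all(is.finite(values))) stop("curve contains non-finite values")
  structure(list(values = values, grid = grid, source = source),
            class = "signal_curve")
}

#' @export
print.signal_curve <- function(x, ...) {
  cat(sprintf("<signal_curve> %s, %d frames, peak %.3g\n",
              x$source, length(x$values), max(x$values)))
  invisible(x)
}

#' Reconstruct the de-noised mean curve of a region from the factorization
#'
#' The region curve is the mean of the factorized weight rows over the
#' region's voxels multiplied into the temporal patterns, using all
#' patterns. Because the product discards the residual, the curve is
#' effectively de-noised relative to the raw voxel mean.
#'
#' @param nmf An `nmf_result`.
#' @param mask Region [mask_volume()]; must be non-empty and contained in
#'   the factorized (prostate) voxel set.
#' @return A [signal_curve()] with source `"roi_reconstructed"`.
#' @export
reconstruct_curve <- function(nmf, mask) {
  stopifnot(inherits(nmf, "nmf_result"))
  m <- as_mask_data(mask)
  vox <- which(m)
  if (length(vox) == 0L) stop("empty region mask")
  rows <- match(vox, nmf$voxels)
  if (anyNA(rows)) stop("region mask extends outside the factorized voxels")
  wbar <- colMeans(nmf$W[rows, , drop = FALSE])
  signal_curve(as.numeric(wbar %*% nmf$S), nmf$grid, "roi_reconstructed")
}

#' Mean baseline-corrected raw curve of a region
#'
#' Per-frame mean of the voxel curves in the mask after subtracting each
#' voxel's pre-contrast baseline (no non-negativity clipping: the mean of
#' a flat noisy region should be zero, not positive).
#'
#' @param series A [dce_series()].
#' @param mask Region [mask_volume()], non-empty.
#' @param source Source label for the result. Default `"roi_raw_mean"`.
#' @return A [signal_curve()].
#' @export
mean_raw_curve <- function(series, mask, source = "roi_raw_mean") {
  stopifnot(inherits(series, "dce_series"))
  m <- as_mask_data(mask)
  d <- dim(series$data)
  if (!identical(dim(m), d[1:3])) stop("mask is on a different grid")
  vox <- which(m)
  if (length(vox) == 0L) stop("empty region mask")
  flat <- matrix(series$data, nrow = prod(d[1:3]), ncol = d[4])
  curves <- flat[vox, , drop = FALSE]
  base <- rowMeans(curves[, seq_len(series$grid$n_pre), drop = FALSE])
  signal_curve(colMeans(curves - base), series$grid, source)
}

#' Trapezoidal area under a measured curve on a time window
#'
#' Integrates the piecewise-linear interpolant of the curve between `t1`
#' and `t2` seconds; window endpoints falling between frames are linearly
#' interpolated.
#'
#' @param curve A [signal_curve()].
#' @param t1,t2 Window limits in seconds, `t1 < t2`, within the grid span.
#' @return Area in intensity x seconds.
#' @export
curve_auc <- function(curve, t1, t2) {
  stopifnot(inherits(curve, "signal_curve"))
  times <- curve$grid$times
  if (t1 >= t2) stop("t1 must be smaller than t2")
  if (t1 < times[1] - 1e-9 || t2 > times[length(times)] + 1e-9) {
    stop("window outside the time grid")
  }
  inner <- times[times > t1 & times < t2]
  tt <- c(t1, inner, t2)
  vv <- stats::approx(times, curve$values, xout = tt)$y
  sum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2)
}

biexp_model <- function(times, s0, A, t0, k1, k2) {
  dt <- pmax(times - t0, 0)
  s0 + A * (exp(-k2 * dt) - exp(-k1 * dt))
}

#' Fit the bi-exponential enhancement model to a curve
#'
#' Nonlinear least squares of
#' `S(t) = s0 + A * (exp(-k2*(t-t0)) - exp(-k1*(t-t0)))` (flat at `s0`
#' before onset `t0`) to a signal-time curve, by bounded quasi-Newton
#' optimization from five deterministic starting points; the best
#' residual wins, ties by lower `k1`. Bounds: `s0 >= 0`,
#' `0 <= t0 <= 120` s, `k1` in (1e-4, 1], `0 <= k2 < k1` (parameterized as
#' `k2 = r * k1`, `r` in [0, 0.99]).
#'
#' Derived quantities: time-to-peak `tau = log(k1/k2)/(k1-k2)`, peak
#' intensity `sm = S(t0 + tau)`, and the mean model washout slope from
#' peak to the last frame,
#' `wo_biexp = (S(t0+tau) - S(t_end)) / (t_end - t0 - tau)` (0 when the
#' model never peaks inside the acquisition).
#'
#' @param curve A [signal_curve()].
#' @return An object of class `biexp_params`: `s0`, `sm`, `t0`, `tau`,
#'   `wo_biexp`, generative `A`, `k1`, `k2`, `rmse`, `valid` and the grid.
#'   A non-enhancing curve (no value above the first frame) yields
#'   `valid = FALSE` with NA parameters.
#' @export
fit_biexp <- function(curve) {
  stopifnot(inherits(curve, "signal_curve"))
  times <- curve$grid$times
  v <- curve$values
  t_end <- times[length(times)]
  invalid <- structure(list(s0 = NA_real_, sm = NA_real_, t0 = NA_real_,
                            tau = NA_real_, wo_biexp = NA_real_, A = NA_real_,
                            k1 = NA_real_, k2 = NA_real_, rmse = NA_real_,
                            valid = FALSE, grid = curve$grid),
                       class = "biexp_params")
  if (max(v) <= v[1] + 1e-12 * max(abs(v), 1)) return(invalid)

  vmax <- max(v)
  s0_init <- max(min(v), 0)
  t_rise <- times[which(v > s0_init + 0.1 * (vmax - s0_init))[1]]
  t0_init <- max(0, min(t_rise - 15, 120))
  starts <- list(c(k1 = 0.05, r = 0.20), c(k1 = 0.02, r = 0.05),
                 c(k1 = 0.08, r = 0.40), c(k1 = 0.03, r = 0.10),
                 c(k1 = 0.12, r = 0.60))
  obj <- function(par) {
    pred <- biexp_model(times, par[1], par[2], par[3], par[4], par[5] * par[4])
    sum((pred - v)^2)
  }
  lower <- c(0, 0, 0, 1e-4, 0)
  upper <- c(max(vmax, 1), 20 * max(vmax, 1), 120, 1, 0.99)
  best <- NULL
  for (st in starts) {
    pk <- exp(-st["r"] * st["k1"] * 60) - exp(-st["k1"] * 60)
    A_init <- min(max((vmax - s0_init) / max(pk, 0.05), 1e-6), upper[2])
    par0 <- c(s0_init, A_init, t0_init, st[["k1"]], st[["r"]])
    fit <- try(stats::optim(par0, obj, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = 500, factr = 1e4,
                                           parscale = c(max(vmax, 1) / 10,
                                                        max(vmax, 1), 30,
                                                        0.05, 0.2))),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value * (1 - 1e-9) ||
        (abs(fit$value - best$value) <= 1e-9 * max(best$value, 1e-300) &&
         fit$par[4] < best$par[4])) {
      best <- fit
    }
  }
  if (is.null(best)) return(invalid)
  p <- best$par
  s0 <- p[1]; A <- p[2]; t0 <- p[3]; k1 <- p[4]; k2 <- p[5] * p[4]
  if (k2 < 1e-10) {
    tau <- t_end - t0
    sm <- biexp_model(t_end, s0, A, t0, k1, k2)
    wo <- 0
  } else {
    tau <- log(k1 / k2) / (k1 - k2)
    if (t0 + tau >= t_end - 1e-9) {
      tau <- t_end - t0
      sm <- biexp_model(t_end, s0, A, t0, k1, k2)
      wo <- 0
    } else {
      sm <- biexp_model(t0 + tau, s0, A, t0, k1, k2)
      wo <- (sm - biexp_model(t_end, s0, A, t0, k1, k2)) / (t_end - t0 - tau)
    }
  }
  structure(list(s0 = s0, sm = sm, t0 = t0, tau = tau, wo_biexp = wo,
                 A = A, k1 = k1, k2 = k2,
                 rmse = sqrt(best$value / length(v)), valid = TRUE,
                 grid = curve$grid),
            class = "biexp_params")
}

#' @export
print.biexp_params <- function(x, ...) {
  if (!x$valid) cat("<biexp_params> invalid (non-enhancing curve)\n")
  else cat(sprintf(
    "<biexp_params> s0 = %.3g, sm = %.3g, t0 = %.1f s, tau = %.1f s, wo = %.3g (rmse %.3g)\n",
    x$s0, x$sm, x$t0, x$tau, x$wo_biexp, x$rmse))
  invisible(x)
}

#' Area under the fitted bi-exponential curve
#'
#' Integrates the fitted model on `[t1, t2]` by trapezoid quadrature on a
#' 1 s grid.
#'
#' @param p A valid [fit_biexp()] result.
#' @param t1,t2 Window limits in seconds, `t1 < t2`.
#' @return Area in intensity x seconds.
#' @export
aufc <- function(p, t1, t2) {
  stopifnot(inherits(p, "biexp_params"))
  if (!isTRUE(p$valid)) stop("cannot integrate an invalid fit")
  if (t1 >= t2) stop("t1 must be smaller than t2")
  tt <- seq(t1, t2, by = 1)
  if (tt[length(tt)] < t2) tt <- c(tt, t2)
  vv <- biexp_model(tt, p$s0, p$A, p$t0, p$k1, p$k2)
  sum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2)
}

#' Late-enhancement linear fit
#'
#' Ordinary least squares of intensity against time over the late window
#' (default 270-330 s). The slope is the late washout rate `wo_linear`.
#'
#' @param curve A [signal_curve()].
#' @param window Two-element window in seconds. Default `c(270, 330)`.
#' @return An object of class `late_linear_fit` with `wo_linear`
#'   (intensity/s), `intercept`, `window` and `n_frames`.
#' @export
fit_late_linear <- function(curve, window = c(270, 330)) {
  stopifnot(inherits(curve, "signal_curve"))
  sel <- curve$grid$times >= window[1] - 1e-9 & curve$grid$times <= window[2] + 1e-9
  if (sum(sel) < 2L) stop("need at least 2 frames inside the late window")
  tt <- curve$grid$times[sel]; vv <- curve$values[sel]
  fit <- stats::lm.fit(cbind(1, tt), vv)
  structure(list(wo_linear = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 window = window, n_frames = sum(sel)),
            class = "late_linear_fit")
}

FEATURE_NAMES <- c("early_auc", "late_auc", "wash_in",
                   "early_aufc", "late_aufc", "wash_out")

compute_raw_features <- function(curve, biexp = NULL) {
  if (is.null(biexp)) biexp <- fit_biexp(curve)
  ll <- try(fit_late_linear(curve), silent = TRUE)
  wo_lin <- if (inherits(ll, "try-error")) NA_real_ else ll$wo_linear
  raw <- c(
    early_auc = curve_auc(curve, 60, 120),
    late_auc = curve_auc(curve, 240, 330),
    wash_in = if (biexp$valid) (biexp$sm - biexp$s0) / biexp$tau else NA_real_,
    early_aufc = if (biexp$valid) aufc(biexp, 60, 120) else NA_real_,
    late_aufc = if (biexp$valid) aufc(biexp, 240, 330) else NA_real_,
    wash_out = -wo_lin
  )
  list(raw = raw, biexp = biexp)
}

#' Six-feature kinetic description of a region curve
#'
#' Computes the six semi-quantitative features of an enhancement curve:
#' early (60-120 s) and late (240-330 s) areas under the measured curve;
#' wash-in slope `(sm - s0)/tau` and early/late areas under the fitted
#' bi-exponential; and wash-out, the negated slope of the late linear fit.
#' When a muscle reference curve is supplied each feature is also returned
#' as the ratio to the muscle feature; a ratio is flagged invalid when the
#' muscle feature is not positive beyond `1e-6 * max|muscle curve|`
#' (a vanishing or sign-degenerate muscle reference); invalid ratios are
#' NA, never infinities.
#'
#' @param curve Region [signal_curve()].
#' @param muscle Optional muscle reference [signal_curve()].
#' @return An object of class `feature_set`: data frame `table` with
#'   columns `feature`, `raw`, `ratio`, `valid`, plus the underlying
#'   bi-exponential fits.
#' @export
feature_set <- function(curve, muscle = NULL) {
  fr <- compute_raw_features(curve)
  tab <- data.frame(feature = FEATURE_NAMES, raw = unname(fr$raw),
                    ratio = NA_real_, valid = !is.na(fr$raw),
                    stringsAsFactors = FALSE)
  muscle_fit <- NULL
  if (!is.null(muscle)) {
    fm <- compute_raw_features(muscle)
    muscle_fit <- fm$biexp
    eps <- 1e-6 * max(abs(muscle$values), .Machine$double.eps)
    # sign-degenerate muscle features (e.g. a negative muscle washout, i.e.
    # muscle still enhancing in the late window) would flip the feature's
    # ordering; such ratios are flagged invalid rather than guessed
    ok <- !is.na(fr$raw) & !is.na(fm$raw) & fm$raw > eps
    tab$ratio[ok] <- fr$raw[ok] / fm$raw[ok]
    tab$valid <- ok
  }
  structure(list(table = tab, biexp = fr$biexp, muscle_biexp = muscle_fit,
                 normalized = !is.null(muscle)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set>%s\n", if (x$normalized) " (muscle-normalized)" else ""))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Extract one feature value from a feature set
#'
#' @param fs A [feature_set()].
#' @param feature Feature name, optionally suffixed `_ratio` (e.g.
#'   `"early_aufc_ratio"`) for the muscle-normalized value.
#' @return The feature value (NA when flagged invalid).
#' @export
get_feature <- function(fs, feature = "early_aufc_ratio") {
  stopifnot(inherits(fs, "feature_set"))
  ratio <- grepl("_ratio$", feature)
  name <- sub("_ratio$", "", feature)
  row <- match(name, fs$table$feature)
  if (is.na(row)) stop("unknown feature: ", feature)
  if (ratio) {
    if (!fs$normalized) stop("no muscle reference supplied; ratio unavailable")
    if (!fs$table$valid[row]) return(NA_real_)
    fs$table$ratio[row]
  } else {
    fs$table$raw[row]
  }
}
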