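#' Mutual information of two intensity samples
#'
#' Shannon mutual information (nats) of the 2D joint histogram of paired
#' intensity samples, the similarity metric driving inter-frame
#' registration. Bin edges span the pooled range of both samples.
#'
#' @param a,b Numeric vectors of equal length.
#' @param n_bins Bins per axis. Default 32.
#' @return Mutual information in nats.
#' @export
mutual_information <- function(a, b, n_bins = 32L) {
  rng <- range(c(a, b))
  if (rng[1] == rng[2]) return(0)
  ia <- pmin(pmax(findInterval(a, seq(rng[1], rng[2], length.out = n_bins + 1L),
                               rightmost.closed = TRUE), 1L), n_bins)
  ib <- pmin(pmax(findInterval(b, seq(rng[1], rng[2], length.out = n_bins + 1L),
                               rightmost.closed = TRUE), 1L), n_bins)
  joint <- tabulate(ia + (ib - 1L) * n_bins, nbins = n_bins * n_bins) /
    length(a)
  pj <- matrix(joint, n_bins, n_bins)
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / (pa[row(pj)[nz]] * pb[col(pj)[nz]])))
}

region_points <- function(region) {
  m <- as_mask_data(region)
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty registration region")
  idx
}

# MI of fixed vs moving-resampled-through-tf, over the region points.
mi_objective <- function(fixed, moving, pts, fixed_vals, tf_center, fill,
                         n_bins = 32L) {
  function(par) {
    tf <- affine2d(par[1], par[2], par[3], exp(par[4]), center = tf_center)
    src <- affine_map(tf, pts[, 1], pts[, 2], dim(moving))
    mv <- bilinear_sample(moving, src$x, src$y, pts[, 3], fill)
    -mutual_information(fixed_vals, mv, n_bins)
  }
}

#' Register one frame to another inside a region
#'
#' Estimates the in-plane affine transform (translation, rotation,
#' isotropic scale about the region centroid) that maximizes the
#' 32-bin-histogram mutual information between the fixed frame and the
#' resampled moving frame over the region voxels. Optimization is
#' derivative-free local search (Nelder-Mead) from a deterministic
#' multi-start at the identity and +/- 2 px single-axis translations, so
#' repeated runs are bit-identical.
#'
#' @param moving,fixed 3D frames on the same grid.
#' @param region Registration region [mask_volume()] (the prostate dilated
#'   by the peri-prostatic margin; see [dilate_mask()]).
#' Two guards keep the estimate meaningful: when the best mutual
#' information exceeds the identity's by less than `min_mi_gain` the
#' registration signal is too weak to trust (noise, or already-aligned
#' frames whose differences are kinetic) and the identity is returned; and
#' an estimate whose largest in-plane displacement over the region is
#' below `snap_px` is snapped to the identity, since sub-resolution
#' resampling only blurs the frame without correcting detectable motion.
#'
#' @param rigid_only Logical; when `TRUE`, only the translation is
#'   optimized. Default `FALSE`.
#' @param max_points Deterministic subsampling cap on the number of region
#'   voxels entering the metric. Default 8000.
#' @param min_mi_gain Minimum mutual-information gain (nats) over the
#'   identity for the estimate to be returned. Default 0.05.
#' @param snap_px Displacement (pixels) below which the estimate snaps to
#'   the identity. Default 0.1.
#' @return An [affine2d()] (translation in pixels, about the region
#'   centroid). Returns the identity with a warning if the optimizer fails.
#' @export
register_pair <- function(moving, fixed, region, rigid_only = FALSE,
                          max_points = 8000L, min_mi_gain = 0.05,
                          snap_px = 0.1) {
  pts <- region_points(region)
  ctr <- colMeans(pts)[1:2]
  if (nrow(pts) > max_points) {
    stride <- ceiling(nrow(pts) / max_points)
    pts <- pts[seq(1L, nrow(pts), by = stride), , drop = FALSE]
  }
  fixed_vals <- fixed[pts]
  fill <- min(moving)
  obj <- mi_objective(fixed, moving, pts, fixed_vals, ctr, fill)
  # coarse exhaustive search over integer translations seeds the local
  # optimizer; MI surfaces are multi-modal and a purely local search can
  # stall one pixel short of the optimum
  grid <- expand.grid(tx = -4:4, ty = -4:4)
  gvals <- vapply(seq_len(nrow(grid)),
                  function(i) obj(c(grid$tx[i], grid$ty[i], 0, 0)), numeric(1))
  gbest <- which.min(gvals)
  starts <- unique(list(c(0, 0, 0, 0),
                        c(grid$tx[gbest], grid$ty[gbest], 0, 0),
                        c(2, 0, 0, 0), c(-2, 0, 0, 0),
                        c(0, 2, 0, 0), c(0, -2, 0, 0)))
  best <- NULL
  for (st in starts) {
    fit <- try(
      if (rigid_only) {
        f2 <- function(p) obj(c(p, 0, 0))
        r <- stats::optim(st[1:2], f2, method = "Nelder-Mead",
                          control = list(maxit = 200, reltol = 1e-7))
        list(par = c(r$par, 0, 0), value = r$value)
      } else {
        stats::optim(st, obj, method = "Nelder-Mead",
                     control = list(maxit = 300, reltol = 1e-7))
      }, silent = TRUE)
    if (inherits(fit, "try-error") || !all(is.finite(fit$par))) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    warning("registration optimizer failed; returning identity")
    return(affine2d(center = ctr))
  }
  mi_identity <- -obj(c(0, 0, 0, 0))
  if (-best$value - mi_identity < min_mi_gain) {
    return(affine2d(center = ctr))
  }
  tf <- affine2d(best$par[1], best$par[2], best$par[3], exp(best$par[4]),
                 center = ctr)
  src <- affine_map(tf, pts[, 1], pts[, 2], dim(moving))
  if (max(sqrt((src$x - pts[, 1])^2 + (src$y - pts[, 2])^2)) < snap_px) {
    return(affine2d(center = ctr))
  }
  tf
}

ssd_in_region <- function(a, b, pts) sum((a[pts] - b[pts])^2)
mad_in_region <- function(a, b, pts) mean(abs(a[pts] - b[pts]))

#' Sequential motion correction of a dynamic series
#'
#' Each frame after the first is registered to its *corrected* predecessor
#' (so that accepted corrections compose without re-introducing drift)
#' inside the prostate mask dilated by `margin_mm`. The estimated transform
#' is applied only when it strictly decreases the sum of squared
#' differences (SSD) inside the region; otherwise the frame passes through
#' unchanged. The report records SSD and mean absolute difference (MAD)
#' before/after for every frame pair.
#'
#' @param series A [dce_series()] with at least 2 frames.
#' @param prostate Prostate [mask_volume()].
#' @param margin_mm In-plane dilation of the registration region, in mm.
#'   Default 18.75 (15 pixels at 1.25 mm).
#' @param rigid_only Passed to [register_pair()].
#' @return List with `series` (corrected [dce_series()]) and `report`
#'   (class `motion_report`): per-pair data frame with `frame`, `ssd_before`,
#'   `ssd_after`, `mad_before`, `mad_after`, `pct_change` (percent SSD
#'   decrease), `accepted`, and the list of estimated transforms.
#' @export
correct_series <- function(series, prostate, margin_mm = 18.75,
                           rigid_only = FALSE) {
  stopifnot(inherits(series, "dce_series"))
  Tn <- dim(series$data)[4]
  if (Tn < 2L) stop("series must have at least 2 frames")
  region <- dilate_mask(prostate, margin_mm, series$spacing)
  pts <- region_points(region)
  out <- series$data
  rows <- vector("list", Tn - 1L)
  tfs <- vector("list", Tn - 1L)
  for (j in 2:Tn) {
    fixed <- out[, , , j - 1L]     # corrected predecessor
    moving <- series$data[, , , j]
    tf <- register_pair(moving, fixed, region, rigid_only = rigid_only)
    ssd0 <- ssd_in_region(moving, fixed, pts)
    cand <- resample_frame(moving, tf)
    ssd1 <- ssd_in_region(cand, fixed, pts)
    accepted <- ssd1 < ssd0
    frame_out <- if (accepted) cand else moving
    out[, , , j] <- frame_out
    rows[[j - 1L]] <- data.frame(
      frame = j,
      time_s = series$grid$times[j],
      ssd_before = ssd0,
      ssd_after = if (accepted) ssd1 else ssd0,
      mad_before = mad_in_region(moving, fixed, pts),
      mad_after = mad_in_region(frame_out, fixed, pts),
      pct_change = if (accepted) 100 * (ssd0 - ssd1) / ssd0 else 0,
      accepted = accepted)
    tfs[[j - 1L]] <- if (accepted) tf else affine2d(center = tf$center)
  }
  report <- structure(list(pairs = do.call(rbind, rows), transforms = tfs,
                           margin_mm = margin_mm),
                      class = "motion_report")
  list(series = dce_series(out, series$spacing, series$grid), report = report)
}

#' @export
print.motion_report <- function(x, ...) {
  cat(sprintf("<motion_report> %d frame pairs, %d corrections accepted, median SSD change %.2f%%\n",
              nrow(x$pairs), sum(x$pairs$accepted), stats::median(x$pairs$pct_change)))
  invisible(x)
}

#' Summarize a motion report
#'
#' Median and range of the percent SSD change over the frame pairs;
#' `from_s` restricts to pairs at or after a given frame time (the early
#' bolus-arrival pairs can be summarized separately from the rest).
#'
#' @param report A `motion_report`.
#' @param from_s Only pairs with frame time `>= from_s` seconds. Default 0
#'   (all pairs).
#' @return List with `median_pct`, `range_pct`, `n_pairs`, `n_accepted`.
#' @export
summarize_motion <- function(report, from_s = 0) {
  p <- report$pairs[report$pairs$time_s >= from_s, ]
  list(median_pct = stats::median(p$pct_change),
       range_pct = range(p$pct_change),
       n_pairs = nrow(p),
       n_accepted = sum(p$accepted))
}
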