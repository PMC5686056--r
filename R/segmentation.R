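#' Segmentation configuration for the well-perfused ROI
#'
#' @param method `"purity"` (default) or `"otsu"`.
#' @param beta Purity threshold in percent; one of 40, 50, 60, 70. A voxel
#'   joins the ROI when the well-perfused weight exceeds `beta`% of its
#'   total factorization weight. Default 60, the selected operating point.
#' @param pz_fraction Peripheral-zone assignment threshold in percent; one
#'   of 10, 15, 20. Default 10.
#' @param cleanup_cc Minimum connected-component volume kept, in cc.
#'   Default 0.05.
#' @param min_roi_cc Minimum ROI volume, in cc; smaller ROIs are rejected
#'   from further processing. Default 0.5.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(method = c("purity", "otsu"), beta = 60,
                       pz_fraction = 10, cleanup_cc = 0.05, min_roi_cc = 0.5) {
  method <- match.arg(method)
  if (method == "purity" && !beta %in% c(40, 50, 60, 70)) {
    stop("beta must be one of 40, 50, 60, 70")
  }
  if (!pz_fraction %in% c(10, 15, 20)) {
    stop("pz_fraction must be one of 10, 15, 20")
  }
  if (cleanup_cc < 0 || min_roi_cc <= 0) stop("volume thresholds must be positive")
  structure(list(method = method, beta = beta, pz_fraction = pz_fraction,
                 cleanup_cc = cleanup_cc, min_roi_cc = min_roi_cc),
            class = "seg_config")
}

#' Otsu threshold of a set of positive values
#'
#' Builds a 256-bin histogram over the value range and returns the cut
#' maximizing the between-class variance. Used to threshold the
#' well-perfused weight map; the ROI is `{values > threshold}`.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @param n_bins Number of histogram bins. Default 256.
#' @return The threshold (a bin edge strictly inside the value range).
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (length(unique(values)) < 2L) stop("need at least 2 distinct values")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(values, edges, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  centers <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(h)
  w1 <- sum(h) - w0
  mu0 <- cumsum(h * centers) / pmax(w0, 1)
  mu1 <- (sum(h * centers) - cumsum(h * centers)) / pmax(w1, 1)
  valid <- w0 > 0 & w1 > 0
  bc <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  edges[which.max(bc) + 1L]   # upper edge of the lower class's last bin
}

#' Purity segmentation of the well-perfused weight map
#'
#' A voxel belongs to the ROI when the weight of the well-perfused pattern
#' strictly exceeds `beta`% of the voxel's total weight over all patterns
#' of the same factorization. Voxels with zero total weight are excluded.
#'
#' @param nmf An `nmf_result` with `wp_index` set (see [select_wp()]).
#' @param beta Purity threshold in percent, in (0, 100).
#' @return A [mask_volume()] on the series grid.
#' @export
purity_segment <- function(nmf, beta = 60) {
  stopifnot(inherits(nmf, "nmf_result"))
  if (is.na(nmf$wp_index)) stop("run select_wp() first")
  if (beta <= 0 || beta >= 100) stop("beta must be in (0, 100)")
  tot <- rowSums(nmf$W)
  frac <- ifelse(tot > 0, nmf$W[, nmf$wp_index] / tot, 0)
  sel <- tot > 0 & frac > beta / 100
  m <- array(FALSE, nmf$dim3)
  m[nmf$voxels[sel]] <- TRUE
  mask_volume(m, "ROI")
}

#' Otsu segmentation of the well-perfused weight map
#'
#' @param nmf An `nmf_result` with `wp_index` set.
#' @return A [mask_volume()]: voxels whose well-perfused weight exceeds the
#'   [otsu_threshold()] of the in-prostate weights.
#' @export
otsu_segment <- function(nmf) {
  stopifnot(inherits(nmf, "nmf_result"))
  if (is.na(nmf$wp_index)) stop("run select_wp() first")
  w <- nmf$W[, nmf$wp_index]
  thr <- otsu_threshold(w)
  m <- array(FALSE, nmf$dim3)
  m[nmf$voxels[w > thr]] <- TRUE
  mask_volume(m, "ROI")
}

#' Label connected components of a 3D mask (26-connectivity)
#'
#' @param mask A [mask_volume()] or 3D logical array.
#' @return Integer array of the same shape: 0 background, 1..n component ids.
#' @export
label_components <- function(mask) {
  m <- as_mask_data(mask)
  d <- dim(m)
  lab <- array(0L, d)
  # 26-neighborhood offsets in linear index space, with coordinate checks
  nb <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  todo <- which(m)
  current <- 0L
  for (start in todo) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- start
    lab[start] <- current
    while (length(queue)) {
      v <- queue
      queue <- integer(0)
      ai <- arrayInd(v, d)
      for (r in seq_len(nrow(nb))) {
        i <- ai[, 1] + nb[r, 1]; j <- ai[, 2] + nb[r, 2]; k <- ai[, 3] + nb[r, 3]
        ok <- i >= 1L & i <= d[1] & j >= 1L & j <= d[2] & k >= 1L & k <= d[3]
        if (!any(ok)) next
        lin <- i[ok] + (j[ok] - 1L) * d[1] + (k[ok] - 1L) * d[1] * d[2]
        new <- lin[m[lin] & lab[lin] == 0L]
        if (length(new)) {
          lab[new] <- current
          queue <- c(queue, new)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

#' Remove small disconnected components from a mask
#'
#' Deletes 26-connected components whose volume is below `min_cc` cubic
#' centimetres. Never increases the mask; idempotent.
#'
#' @param mask A [mask_volume()] or 3D logical array.
#' @param min_cc Minimum component volume kept, in cc.
#' @param spacing Voxel spacing in mm.
#' @return The cleaned [mask_volume()].
#' @export
cleanup_components <- function(mask, min_cc = 0.05, spacing = c(1.25, 1.25, 2.5)) {
  if (min_cc < 0) stop("min_cc must be >= 0")
  m <- as_mask_data(mask)
  label <- if (inherits(mask, "mask_volume")) mask$label else "ROI"
  if (!any(m) || min_cc == 0) return(mask_volume(m, label))
  lab <- label_components(m)
  sizes <- tabulate(lab[lab > 0L])
  vox_cc <- prod(spacing) / 1000
  keep <- which(sizes * vox_cc >= min_cc)
  mask_volume(array(lab %in% keep, dim(m)), label)
}

#' Volume gate and zonal assignment of the well-perfused ROI
#'
#' Applies the minimum-volume rejection gate, assigns the (cleaned) ROI as
#' one object to the peripheral zone when more than `pz_fraction`% of it
#' lies inside the PZ (transition zone otherwise), and derives the
#' normal-appearing-tissue masks of both zones.
#'
#' @param roi Cleaned ROI [mask_volume()].
#' @param pz,tz Zone [mask_volume()]s on the same grid.
#' @param cfg A [seg_config()].
#' @param spacing Voxel spacing in mm.
#' @param volume_before_cc Optional ROI volume before cleanup, carried into
#'   the report.
#' @return An object of class `seg_result`: `roi_wp`, `zone` ("PZ"/"TZ" or
#'   NA when rejected/empty), `pz_roi_wp`, `tz_roi_wp`, `nat_pz`, `nat_tz`,
#'   `volume_cc` (after cleanup), `volume_before_cc`, `pz_overlap_fraction`
#'   and `rejected`.
#' @export
gate_and_assign <- function(roi, pz, tz, cfg = seg_config(),
                            spacing = c(1.25, 1.25, 2.5),
                            volume_before_cc = NA_real_) {
  r <- as_mask_data(roi); p <- as_mask_data(pz); z <- as_mask_data(tz)
  if (!identical(dim(r), dim(p)) || !identical(dim(r), dim(z))) {
    stop("masks are on different grids")
  }
  vol <- volume_cc(r, spacing)
  n_roi <- sum(r)
  rejected <- vol < cfg$min_roi_cc
  frac_pz <- if (n_roi > 0) sum(r & p) / n_roi else NA_real_
  zone <- if (n_roi == 0) NA_character_
          else if (frac_pz > cfg$pz_fraction / 100) "PZ" else "TZ"
  empty <- array(FALSE, dim(r))
  structure(list(
    roi_wp = mask_volume(r, "ROI"),
    zone = zone,
    pz_roi_wp = mask_volume(if (identical(zone, "PZ")) r else empty, "ROI"),
    tz_roi_wp = mask_volume(if (identical(zone, "TZ")) r else empty, "ROI"),
    nat_pz = mask_volume(p & !r, "NAT_PZ"),
    nat_tz = mask_volume(z & !r, "NAT_TZ"),
    volume_cc = vol,
    volume_before_cc = volume_before_cc,
    pz_overlap_fraction = frac_pz,
    rejected = rejected,
    config = cfg), class = "seg_result")
}

#' @export
print.seg_result <- function(x, ...) {
  cat(sprintf("<seg_result> %.3f cc, zone %s%s\n", x$volume_cc,
              ifelse(is.na(x$zone), "-", x$zone),
              if (x$rejected) " [REJECTED: below minimum volume]" else ""))
  invisible(x)
}

#' Segment the well-perfused ROI from a factorization result
#'
#' Full segmentation stage: threshold the well-perfused weight map (purity
#' or Otsu), remove small disconnected components, apply the volume gate
#' and assign the zone.
#'
#' @param nmf An `nmf_result` with `wp_index` set.
#' @param pz,tz Zone [mask_volume()]s.
#' @param cfg A [seg_config()].
#' @param spacing Voxel spacing in mm.
#' @return A `seg_result` (see [gate_and_assign()]).
#' @export
segment_wp <- function(nmf, pz, tz, cfg = seg_config(),
                       spacing = c(1.25, 1.25, 2.5)) {
  roi <- if (cfg$method == "purity") purity_segment(nmf, cfg$beta)
         else otsu_segment(nmf)
  vol_before <- volume_cc(roi, spacing)
  roi <- cleanup_components(roi, cfg$cleanup_cc, spacing)
  gate_and_assign(roi, pz, tz, cfg, spacing, volume_before_cc = vol_before)
}
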