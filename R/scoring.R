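#' Fit a 1-10 scoring scale to cohort feature values
#'
#' The scale is bounded by the empirical 5th and 95th percentiles (linear
#' interpolation, type-7 quantiles) of the feature's distribution over a
#' cohort, divided into 10 uniform bins. Values below/above the bounds
#' score 1 and 10. The scale is a persisted artifact (JSON) fit once on a
#' cohort and applied to new cases.
#'
#' @param values Numeric feature values, `>= 20` non-missing.
#' @param name Feature name recorded in the scale.
#' @return An object of class `score_scale` with `feature`, `lower`,
#'   `upper`, `n_bins = 10`, `percentiles = c(5, 95)` and the interpolation
#'   convention.
#' @export
fit_scale <- function(values, name = "feature") {
  values <- values[is.finite(values)]
  if (length(values) < 20L) stop("need at least 20 cohort values to fit a scale")
  if (diff(range(values)) == 0) stop("all cohort values are equal")
  q <- stats::quantile(values, c(0.05, 0.95), type = 7, names = FALSE)
  structure(list(feature = name, lower = q[1], upper = q[2], n_bins = 10L,
                 percentiles = c(5, 95), interpolation = "linear (type 7)"),
            class = "score_scale")
}

#' @export
print.score_scale <- function(x, ...) {
  cat(sprintf("<score_scale> %s: [%.4g, %.4g] in %d bins\n",
              x$feature, x$lower, x$upper, x$n_bins))
  invisible(x)
}

#' Save / load a scoring scale as JSON
#' @param scale A [fit_scale()] result.
#' @param path JSON file path.
#' @return `write_scale`: `path` invisibly; `read_scale`: the `score_scale`.
#' @export
write_scale <- function(scale, path) {
  jsonlite::write_json(unclass(scale), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scale
#' @export
read_scale <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(s, class = "score_scale")
}

#' Score feature values on the 1-10 scale
#'
#' Bins are half-open `[edge, next_edge)` with the top bin closed, so the
#' lower bound scores 1 and the upper bound scores 10; out-of-range values
#' clamp to 1 and 10.
#'
#' @param x Numeric value(s).
#' @param scale A [fit_scale()] result.
#' @return Integer score(s) in 1..10.
#' @export
score_value <- function(x, scale) {
  stopifnot(inherits(scale, "score_scale"))
  if (any(!is.finite(x))) stop("cannot score non-finite values")
  raw <- 1L + floor(scale$n_bins * (x - scale$lower) /
                      (scale$upper - scale$lower))
  pmin(pmax(as.integer(raw), 1L), scale$n_bins)
}

#' Per-voxel aggressiveness map
#'
#' Generalizes a region-level feature value `F` to every voxel of the
#' prostate through the well-perfused weight map: with
#' `omega = mean(W_wp over ROI_wp)`, the continuous map is
#' `W_wp * F / omega`, so its mean over the ROI equals `F` by construction
#' and is invariant to a global rescaling of the weights. The continuous
#' values are then binned to 1-10 scores by [score_value()]; voxels
#' outside the weighted prostate carry the background sentinel 0, never a
#' score.
#'
#' @param nmf An `nmf_result` with `wp_index` set.
#' @param seg A non-rejected `seg_result`.
#' @param F Feature value of the ROI curve (see [feature_set()]).
#' @param scale A [fit_scale()] result for that feature.
#' @return An object of class `aggressiveness_map`: `continuous` (3D),
#'   `scores` (3D integer, 0 outside), `omega`, `F`, `feature`.
#' @export
make_map <- function(nmf, seg, F, scale) {
  stopifnot(inherits(nmf, "nmf_result"), inherits(seg, "seg_result"))
  if (seg$rejected) stop("segmentation was rejected; no map is defined")
  if (!is.finite(F)) stop("feature value F must be finite")
  if (is.null(nmf$W_wp)) stop("run select_wp() first")
  roi <- seg$roi_wp$data
  omega <- mean(nmf$W_wp[roi])
  if (!is.finite(omega) || omega == 0) stop("mean well-perfused weight over the ROI is zero")
  cont <- nmf$W_wp * (F / omega)
  scores <- array(0L, dim(cont))
  inside <- nmf$W_wp > 0
  scores[inside] <- score_value(cont[inside], scale)
  structure(list(continuous = cont, scores = scores, omega = omega, F = F,
                 feature = scale$feature),
            class = "aggressiveness_map")
}

#' @export
print.aggressiveness_map <- function(x, ...) {
  sc <- x$scores[x$scores > 0]
  cat(sprintf("<aggressiveness_map> %s, F = %.4g, omega = %.4g, scores %d-%d\n",
              x$feature, x$F, x$omega,
              if (length(sc)) min(sc) else NA, if (length(sc)) max(sc) else NA))
  invisible(x)
}

#' Score biopsy regions against the aggressiveness map
#'
#' For each biopsy-track mask: intersect it with the well-perfused ROI
#' (the usROI), compute the kinetic feature set of the usROI curve (raw
#' voxel mean by default, muscle-normalized when a muscle curve is given),
#' and average the continuous map over the biopsy region. Biopsies whose
#' usROI is empty are flagged and carry no features.
#'
#' @param map An [make_map()] result.
#' @param nmf The `nmf_result` of the same case.
#' @param seg The `seg_result` of the same case.
#' @param series The (motion-corrected) [dce_series()].
#' @param biopsies List of entries, each with `mask` (a [mask_volume()] or
#'   3D logical array) and optionally `label` (a [gleason_label()]) and
#'   `id`.
#' @param muscle Optional muscle [signal_curve()] used for normalization.
#' @param reconstructed Use the factorization-reconstructed usROI curve
#'   instead of the raw mean. Default `FALSE`.
#' @return A data frame with one row per biopsy: `id`, `n_voxels`,
#'   `usroi_voxels`, `empty_usroi`, `map_mean`, the six raw features and
#'   (if normalized) the six ratio features, and Gleason fields when
#'   labels are present. The per-biopsy [feature_set()]s are attached as
#'   attribute `"feature_sets"`.
#' @export
score_biopsies <- function(map, nmf, seg, series, biopsies, muscle = NULL,
                           reconstructed = FALSE) {
  roi <- seg$roi_wp$data
  rows <- list()
  fsets <- list()
  for (i in seq_along(biopsies)) {
    b <- biopsies[[i]]
    bm <- as_mask_data(b$mask)
    us <- bm & roi
    id <- if (!is.null(b$id)) b$id else sprintf("biopsy_%02d", i)
    inside <- bm & map$continuous > 0
    map_mean <- if (any(inside)) mean(map$continuous[inside]) else NA_real_
    row <- data.frame(id = id, n_voxels = sum(bm), usroi_voxels = sum(us),
                      empty_usroi = !any(us), map_mean = map_mean,
                      stringsAsFactors = FALSE)
    if (any(us)) {
      crv <- if (reconstructed) reconstruct_curve(nmf, us)
             else mean_raw_curve(series, us)
      fs <- feature_set(crv, muscle)
      fsets[[id]] <- fs
      vals <- stats::setNames(fs$table$raw, paste0(fs$table$feature, "_raw"))
      row <- cbind(row, as.data.frame(as.list(vals)))
      if (fs$normalized) {
        rv <- stats::setNames(fs$table$ratio, paste0(fs$table$feature, "_ratio"))
        row <- cbind(row, as.data.frame(as.list(rv)))
      }
    }
    if (!is.null(b$label)) {
      row$gleason_total <- b$label$total
      row$gs_group3 <- b$label$group3
      row$gs_group4 <- b$label$group4
      row$gs_binary <- b$label$binary
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    missing_cols <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    for (mc in missing_cols) r[[mc]] <- NA
    r[, unique(unlist(lapply(rows, names)))]
  }))
  attr(out, "feature_sets") <- fsets
  out
}

#' Write an aggressiveness map to NIfTI
#'
#' @param map An [make_map()] result.
#' @param path Output path for the 1-10 score volume; the continuous map
#'   is written next to it with suffix `_continuous`.
#' @param spacing Voxel spacing in mm.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, spacing = c(1.25, 1.25, 2.5)) {
  img <- RNifti::asNifti(map$scores)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "int16")
  cpath <- sub("(\\.nii(\\.gz)?)$", "_continuous\\1", path)
  img2 <- RNifti::asNifti(map$continuous)
  RNifti::pixdim(img2) <- spacing
  RNifti::writeNifti(img2, cpath, datatype = "double")
  invisible(path)
}
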