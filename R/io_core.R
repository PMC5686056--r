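#' Acquisition time grid for a dynamic series
#'
#' Describes when each frame of a dynamic contrast-enhanced series was
#' acquired and how many frames precede contrast arrival. Times are in
#' seconds relative to the first frame.
#'
#' @param times Numeric vector of frame times in seconds; must start at 0 and
#'   be strictly increasing.
#' @param n_pre Number of pre-contrast (baseline) frames, `>= 1` and smaller
#'   than the number of frames. Default 2.
#' @return An object of class `time_grid`.
#' @examples
#' time_grid()                      # 12 frames at 30 s
#' time_grid(seq(0, 374, by = 34))  # 34 s spacing variant
#' @export
time_grid <- function(times = seq(0, 330, by = 30), n_pre = 2L) {
  times <- as.numeric(times)
  if (length(times) < 2L) stop("time grid needs at least 2 frames")
  if (times[1] != 0) stop("times must start at 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  n_pre <- as.integer(n_pre)
  if (n_pre < 1L || n_pre >= length(times)) {
    stop("n_pre must satisfy 1 <= n_pre < number of frames")
  }
  structure(list(times = times, n_pre = n_pre), class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %d frames, t = %g..%g s, %d pre-contrast\n",
              length(x$times), x$times[1], x$times[length(x$times)], x$n_pre))
  invisible(x)
}

#' 4D dynamic contrast-enhanced series
#'
#' Container for a 4D (x, y, z, time) intensity array together with voxel
#' spacing in mm and its acquisition [time_grid()]. Intensities are in
#' arbitrary scanner units and are never rescaled implicitly.
#'
#' @param data 4D numeric array, non-negative and finite.
#' @param spacing Numeric triple `(dx, dy, dz)` in mm, all positive.
#' @param grid A [time_grid()] whose length matches `dim(data)[4]`.
#' @return An object of class `dce_series`.
#' @export
dce_series <- function(data, spacing = c(1.25, 1.25, 2.5), grid = time_grid()) {
  if (length(dim(data)) != 4L) stop("expected 4D series")
  if (!all(is.finite(data))) stop("series contains non-finite voxels")
  if (any(data < 0)) stop("series intensities must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be 3 positive values (mm)")
  }
  if (!inherits(grid, "time_grid")) grid <- do.call(time_grid, grid)
  if (dim(data)[4] != length(grid$times)) {
    stop("number of frames does not match the time grid")
  }
  structure(list(data = data, spacing = spacing, grid = grid),
            class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dce_series> %dx%dx%d voxels x %d frames, spacing %g x %g x %g mm\n",
              d[1], d[2], d[3], d[4], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' 3D binary mask on the series grid
#'
#' @param data 3D logical (or 0/1) array.
#' @param label Character label, one of the anatomical / derived regions:
#'   prostate, PZ, TZ, GM, ROI, NAT_PZ, NAT_TZ, biopsy.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(data, label = "ROI") {
  if (length(dim(data)) != 3L) stop("mask must be a 3D array")
  mode(data) <- "logical"
  if (anyNA(data)) stop("mask contains NA")
  allowed <- c("prostate", "PZ", "TZ", "GM", "ROI", "NAT_PZ", "NAT_TZ", "biopsy")
  if (!label %in% allowed) {
    stop("unknown mask label: ", label)
  }
  structure(list(data = data, label = label), class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("<mask_volume> %s: %d voxels of %s\n", x$label,
              sum(x$data), paste(dim(x$data), collapse = "x")))
  invisible(x)
}

as_mask_data <- function(mask) {
  if (inherits(mask, "mask_volume")) mask$data else {
    m <- mask; mode(m) <- "logical"; m
  }
}

#' Gleason score label with grouped encodings
#'
#' Histopathological grade with the ordinal groupings used for association
#' analyses: a three-level grouping (6, 3+4, >3+4), a four-level grouping
#' (6, 3+4, 4+3, 8-10) and the binary indolent (total 6) vs aggressive
#' (total >= 7) split.
#'
#' @param primary,secondary Integer Gleason grades (3-5).
#' @return An object of class `gleason_label` with fields `total`, `group3`
#'   (1-3), `group4` (1-4) and `binary` ("indolent"/"aggressive").
#' @examples
#' gleason_label(3, 4)$group4  # 2
#' gleason_label(4, 3)$binary  # "aggressive"
#' @export
gleason_label <- function(primary, secondary) {
  primary <- as.integer(primary); secondary <- as.integer(secondary)
  if (primary < 3 || primary > 5 || secondary < 3 || secondary > 5) {
    stop("Gleason grades must be in 3..5")
  }
  total <- primary + secondary
  group3 <- if (total == 6) 1L else if (primary == 3 && secondary == 4) 2L else 3L
  group4 <- if (total == 6) 1L else if (primary == 3 && secondary == 4) 2L
            else if (primary == 4 && secondary == 3) 3L else 4L
  binary <- if (total == 6) "indolent" else "aggressive"
  structure(list(primary = primary, secondary = secondary, total = total,
                 group3 = group3, group4 = group4, binary = binary),
            class = "gleason_label")
}

#' Read a 4D dynamic series from NIfTI
#'
#' Voxel spacing is taken from the NIfTI header. The time grid comes from a
#' JSON sidecar (`<stem>.json` with fields `times` and `n_pre`) when present,
#' or from the `grid` argument.
#'
#' @param path Path to a 4D `.nii` / `.nii.gz` file.
#' @param grid Optional [time_grid()]; overrides any sidecar.
#' @return A [dce_series()].
#' @export
read_series <- function(path, grid = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) stop("expected 4D series, got ", length(dim(arr)), "D")
  if (!all(is.finite(arr))) stop("series contains non-finite voxels")
  spacing <- RNifti::pixdim(img)[1:3]
  if (is.null(grid)) {
    sidecar <- sidecar_path(path)
    if (file.exists(sidecar)) {
      cfg <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      grid <- time_grid(cfg$times, cfg$n_pre)
    } else {
      grid <- time_grid(seq(0, by = 30, length.out = dim(arr)[4]))
    }
  }
  dce_series(arr, spacing = spacing, grid = grid)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write a dynamic series (and its time-grid sidecar) to NIfTI
#'
#' @param series A [dce_series()].
#' @param path Output `.nii` / `.nii.gz` path; a JSON sidecar with the time
#'   grid is written next to it.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "dce_series"))
  dt <- diff(series$grid$times)[1]
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$spacing, dt)
  RNifti::writeNifti(img, path, datatype = "double")
  jsonlite::write_json(list(times = series$grid$times, n_pre = series$grid$n_pre),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a 3D binary mask as NIfTI
#'
#' @param path NIfTI path.
#' @param label Mask label (see [mask_volume()]).
#' @return [read_mask()]: a [mask_volume()]; [write_mask()]: `path`.
#' @export
read_mask <- function(path, label = "ROI") {
  if (!file.exists(path)) stop("file not found: ", path)
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L) stop("expected 3D mask, got ", length(dim(arr)), "D")
  mask_volume(arr > 0.5, label = label)
}

#' @rdname read_mask
#' @param mask A [mask_volume()].
#' @param spacing Voxel spacing triple in mm, written to the header.
#' @export
write_mask <- function(mask, path, spacing = c(1.25, 1.25, 2.5)) {
  stopifnot(inherits(mask, "mask_volume"))
  img <- RNifti::asNifti(array(as.integer(mask$data), dim(mask$data)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Mask volume in cubic centimetres
#'
#' @param mask A [mask_volume()] or 3D logical array.
#' @param spacing Voxel spacing `(dx, dy, dz)` in mm.
#' @return Volume in cc: `count * dx*dy*dz / 1000`.
#' @examples
#' m <- array(FALSE, c(4, 4, 4)); m[1:2, 1, 1] <- TRUE
#' volume_cc(m, c(1.25, 1.25, 2.5))
#' @export
volume_cc <- function(mask, spacing = c(1.25, 1.25, 2.5)) {
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be positive")
  sum(as_mask_data(mask)) * prod(spacing) / 1000
}

#' In-plane (slice-wise) binary dilation by a physical radius
#'
#' Dilates each axial slice with a disc structuring element of pixel radius
#' `ceiling(radius_mm / dx)`. The dilation is 2D because the peri-prostatic
#' registration margin is defined in the in-plane resolution; with the
#' default 1.25 mm pixels an 18.75 mm margin is exactly 15 pixels.
#'
#' @param mask A [mask_volume()] or 3D logical array.
#' @param radius_mm Non-negative dilation radius in mm.
#' @param spacing Voxel spacing in mm (only `dx` is used).
#' @return A [mask_volume()] that is a superset of the input.
#' @export
dilate_mask <- function(mask, radius_mm, spacing = c(1.25, 1.25, 2.5)) {
  if (radius_mm < 0) stop("radius_mm must be >= 0")
  m <- as_mask_data(mask)
  label <- if (inherits(mask, "mask_volume")) mask$label else "ROI"
  r <- as.integer(ceiling(radius_mm / spacing[1] - 1e-9))
  if (r == 0L || !any(m)) return(mask_volume(m, label))
  # disc offsets: all integer (di, dj) with di^2 + dj^2 <= r^2
  off <- expand.grid(di = -r:r, dj = -r:r)
  off <- off[off$di^2 + off$dj^2 <= r^2, ]
  d <- dim(m)
  out <- array(FALSE, d)
  idx <- which(m, arr.ind = TRUE)
  for (s in seq_len(nrow(off))) {
    i <- idx[, 1] + off$di[s]
    j <- idx[, 2] + off$dj[s]
    ok <- i >= 1L & i <= d[1] & j >= 1L & j <= d[2]
    out[cbind(i[ok], j[ok], idx[ok, 3])] <- TRUE
  }
  mask_volume(out, label)
}

#' Derive the transition zone from prostate and peripheral-zone masks
#'
#' The transition zone is the prostate minus the peripheral zone. Voxels of
#' the PZ mask lying outside the prostate are an error: zonal contours must
#' be nested.
#'
#' @param prostate,pz [mask_volume()]s on the same grid.
#' @return A TZ [mask_volume()].
#' @export
derive_tz <- function(prostate, pz) {
  p <- as_mask_data(prostate); z <- as_mask_data(pz)
  if (!identical(dim(p), dim(z))) stop("masks are on different grids")
  if (any(z & !p)) stop("PZ mask is not contained in the prostate mask")
  mask_volume(p & !z, "TZ")
}
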