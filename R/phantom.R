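#' Bi-exponential tissue enhancement kinetics
#'
#' Generative parameters of a contrast-enhancement curve: baseline intensity
#' `s0`, amplitude `A`, uptake rate `k1` (1/s), washout rate `k2` (1/s) and
#' enhancement onset `t0` (s). The signal is flat at `s0` until `t0` and then
#' follows a difference of exponentials,
#' `S(t) = s0 + A * (exp(-k2*(t-t0)) - exp(-k1*(t-t0)))`.
#' Derived quantities: time-to-peak `tau = log(k1/k2)/(k1-k2)` after onset
#' and peak intensity `sm = S(t0 + tau)`.
#'
#' @param s0 Baseline intensity (arbitrary units), `>= 0`.
#' @param A Enhancement amplitude, `>= 0`.
#' @param k1 Uptake rate constant (1/s), `> k2`.
#' @param k2 Washout rate constant (1/s), `>= 0`.
#' @param t0 Enhancement onset time (s), `>= 0`.
#' @return An object of class `tissue_kinetics` with derived `tau` and `sm`.
#' @examples
#' tk <- tissue_kinetics(s0 = 100, A = 160, k1 = 0.04, k2 = 0.003, t0 = 45)
#' tk$tau
#' @export
tissue_kinetics <- function(s0, A, k1, k2, t0) {
  if (k1 <= k2) stop("k1 must exceed k2")
  if (k2 < 0) stop("k2 must be >= 0")
  if (A < 0 || s0 < 0 || t0 < 0) stop("s0, A, t0 must be >= 0")
  tau <- if (A == 0) NA_real_
         else if (k2 == 0) Inf
         else log(k1 / k2) / (k1 - k2)
  sm <- if (A == 0 || is.na(tau)) s0
        else if (is.infinite(tau)) s0 + A
        else s0 + A * (exp(-k2 * tau) - exp(-k1 * tau))
  structure(list(s0 = s0, A = A, k1 = k1, k2 = k2, t0 = t0,
                 tau = tau, sm = sm),
            class = "tissue_kinetics")
}

#' Default tissue kinetics presets
#'
#' Named kinetic parameter sets for the phantom: non-enhancing background,
#' slowly/weakly enhancing gluteus muscle, benign peripheral- and
#' transition-zone tissue, and four lesion grades. Lesions follow the
#' classic "type 3" malignant curve — rapid early enhancement followed by
#' pronounced washout — while benign tissue and muscle enhance later and
#' progressively. Lesion parameters are graded so that wash-in slope,
#' washout magnitude and both early and late enhancement increase strictly
#' with Gleason grade 6 < 3+4 < 4+3 < 8. The values are package constants
#' chosen to emulate typical prostate enhancement at 30 s sampling; they
#' are not measured population parameters.
#'
#' @return Named list of [tissue_kinetics()]: `background`, `muscle`,
#'   `benign_pz`, `benign_tz`, `lesion_g6`, `lesion_g34`, `lesion_g43`,
#'   `lesion_g8`.
#' @export
kinetics_presets <- function() {
  list(
    background = tissue_kinetics(s0 = 80,  A = 0,   k1 = 0.010, k2 = 0,      t0 = 0),
    muscle     = tissue_kinetics(s0 = 100, A = 60,  k1 = 0.012, k2 = 0.0020, t0 = 75),
    benign_pz  = tissue_kinetics(s0 = 100, A = 90,  k1 = 0.013, k2 = 0.0008, t0 = 60),
    benign_tz  = tissue_kinetics(s0 = 100, A = 120, k1 = 0.016, k2 = 0.0012, t0 = 55),
    lesion_g6  = tissue_kinetics(s0 = 100, A = 160, k1 = 0.022, k2 = 0.0085, t0 = 45),
    lesion_g34 = tissue_kinetics(s0 = 100, A = 190, k1 = 0.026, k2 = 0.0087, t0 = 45),
    lesion_g43 = tissue_kinetics(s0 = 100, A = 220, k1 = 0.030, k2 = 0.0089, t0 = 45),
    lesion_g8  = tissue_kinetics(s0 = 100, A = 250, k1 = 0.034, k2 = 0.0091, t0 = 45)
  )
}

lesion_preset_for_grade <- function(grade, presets = kinetics_presets()) {
  key <- switch(as.character(grade),
                "6" = "lesion_g6", "3+4" = "lesion_g34",
                "4+3" = "lesion_g43", "8" = "lesion_g8",
                stop("unknown lesion grade: ", grade))
  presets[[key]]
}

#' Evaluate a kinetic enhancement curve on a time grid
#'
#' @param p A [tissue_kinetics()].
#' @param grid A [time_grid()], or a numeric vector of times in seconds.
#' @return Numeric intensity vector, one value per time point.
#' @examples
#' kinetic_curve(kinetics_presets()$lesion_g6, time_grid())
#' @export
kinetic_curve <- function(p, grid = time_grid()) {
  stopifnot(inherits(p, "tissue_kinetics"))
  times <- if (inherits(grid, "time_grid")) grid$times else as.numeric(grid)
  dt <- pmax(times - p$t0, 0)
  p$s0 + p$A * (exp(-p$k2 * dt) - exp(-p$k1 * dt))
}

# Noise standard deviation giving a target peak-enhancement SNR for a tissue:
# sigma = (sm - s0) / snr.
#' Noise level for a target peak-enhancement signal-to-noise ratio
#'
#' @param p A [tissue_kinetics()] (typically the lesion of interest).
#' @param snr Target ratio of peak enhancement `(sm - s0)` to noise sd.
#' @return The noise standard deviation.
#' @export
sigma_for_snr <- function(p, snr) {
  stopifnot(inherits(p, "tissue_kinetics"), snr > 0)
  (p$sm - p$s0) / snr
}

#' Phantom configuration
#'
#' Describes a synthetic pelvic DCE acquisition: grid geometry, acquisition
#' timing, lesion specifications, per-tissue kinetics, noise model and
#' optional per-frame motion. The prostate is an axial ellipsoid, the
#' peripheral zone its posterior band, and the muscle sample a cuboid outside
#' the gland.
#'
#' @param shape Integer triple, voxel grid size. Default `c(64, 64, 12)`.
#' @param spacing Voxel spacing in mm. Default `c(1.25, 1.25, 2.5)`.
#' @param grid A [time_grid()]; default 12 frames at 30 s with 2 pre-contrast
#'   frames.
#' @param lesions List of lesion specs, each a list with `center_mm`
#'   (xyz, mm), `radius_mm`, `zone` ("PZ"/"TZ") and `grade` (one of
#'   "6", "3+4", "4+3", "8"). Default: one 6.2 mm radius grade 3+4 lesion in
#'   the PZ.
#' @param kinetics Named list of [tissue_kinetics()] overriding
#'   [kinetics_presets()] entries.
#' @param noise List with `model` ("gaussian" or "rician") and `sigma >= 0`.
#' @param motion Optional list of [affine2d()] transforms, one per frame
#'   after the first, injected into the generated series.
#' @param partial_volume Logical; when `TRUE` (default) a fixed 3x3
#'   in-plane binomial kernel blurs the noise-free signal, emulating the
#'   scanner point-spread function. Tissue boundaries then enhance with
#'   mixed kinetics, as real voxels do; set `FALSE` for idealized
#'   piecewise-constant tissue.
#' @param seed Integer seed; identical configurations with identical seeds
#'   generate bit-identical series.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(64L, 64L, 12L),
                           spacing = c(1.25, 1.25, 2.5),
                           grid = time_grid(),
                           lesions = list(list(center_mm = c(40, 53, 16.25),
                                               radius_mm = 6.2,
                                               zone = "PZ", grade = "3+4")),
                           kinetics = list(),
                           noise = list(model = "gaussian", sigma = 0),
                           motion = NULL,
                           partial_volume = TRUE,
                           seed = 1L) {
  kin <- utils::modifyList(kinetics_presets(), kinetics)
  if (is.null(noise$model)) noise$model <- "gaussian"
  if (is.null(noise$sigma)) noise$sigma <- 0
  if (!noise$model %in% c("gaussian", "rician")) {
    stop("noise model must be 'gaussian' or 'rician'")
  }
  if (noise$sigma < 0) stop("noise sigma must be >= 0")
  for (l in lesions) {
    if (is.null(l$radius_mm) || l$radius_mm <= 0) stop("lesion radius must be positive")
    if (!l$zone %in% c("PZ", "TZ")) stop("lesion zone must be PZ or TZ")
  }
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 grid = grid, lesions = lesions, kinetics = kin,
                 noise = noise, motion = motion,
                 partial_volume = isTRUE(partial_volume),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# mm coordinates of voxel centers along one axis
axis_mm <- function(n, d) (seq_len(n) - 0.5) * d

# separable in-plane [1 2 1]/4 binomial blur (edge replication), all frames
blur_inplane <- function(arr4) {
  d <- dim(arr4)
  pad <- function(i, n) pmin(pmax(i, 1L), n)
  i <- seq_len(d[1]); j <- seq_len(d[2])
  a <- 0.25 * arr4[pad(i - 1L, d[1]), , , , drop = FALSE] +
    0.50 * arr4 + 0.25 * arr4[pad(i + 1L, d[1]), , , , drop = FALSE]
  0.25 * a[, pad(j - 1L, d[2]), , , drop = FALSE] +
    0.50 * a + 0.25 * a[, pad(j + 1L, d[2]), , , drop = FALSE]
}

phantom_anatomy <- function(cfg) {
  sh <- cfg$shape; sp <- cfg$spacing
  x <- axis_mm(sh[1], sp[1]); y <- axis_mm(sh[2], sp[2]); z <- axis_mm(sh[3], sp[3])
  ext <- sh * sp
  ctr <- c(ext[1] / 2, ext[2] * 0.56, ext[3] / 2)
  semi <- c(0.275 * ext[1], 0.20 * ext[2], 0.37 * ext[3])
  X <- array(x, sh)
  Y <- aperm(array(y, sh[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(z, sh[c(3, 1, 2)]), c(2, 3, 1))
  r2 <- ((X - ctr[1]) / semi[1])^2 + ((Y - ctr[2]) / semi[2])^2 +
    ((Z - ctr[3]) / semi[3])^2
  prostate <- r2 <= 1
  pz <- prostate & (Y > ctr[2])   # posterior half of the gland
  gm <- X >= 0.06 * ext[1] & X <= 0.25 * ext[1] &
    Y >= 0.69 * ext[2] & Y <= 0.94 * ext[2] &
    Z >= 0.2 * ext[3] & Z <= 0.8 * ext[3]
  if (any(gm & prostate)) stop("internal: muscle sample intersects prostate")
  list(prostate = prostate, pz = pz, tz = prostate & !pz, gm = gm,
       X = X, Y = Y, Z = Z, center = ctr, semi = semi)
}

#' Generate a synthetic pelvic DCE-MRI phantom
#'
#' Builds the anatomy of [phantom_config()], assigns every voxel its
#' tissue's [kinetic_curve()], overwrites lesion voxels with graded lesion
#' kinetics, adds noise, optionally injects inter-frame motion, and returns
#' the series together with the full ground truth.
#'
#' @param cfg A [phantom_config()].
#' @return A list with elements `series` (a [dce_series()]) and `truth`
#'   (masks, per-lesion kinetics and grade, injected transforms, noise-free
#'   tissue-id array and curves).
#' @examples
#' ph <- make_phantom(phantom_config())
#' ph$series
#' @export
make_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  an <- phantom_anatomy(cfg)
  sh <- cfg$shape
  kin <- cfg$kinetics

  # tissue ids: 1 background, 2 muscle, 3 benign PZ, 4 benign TZ, 5.. lesions
  tid <- array(1L, sh)
  tid[an$gm] <- 2L
  tid[an$pz] <- 3L
  tid[an$tz] <- 4L
  tissue_list <- list(kin$background, kin$muscle, kin$benign_pz, kin$benign_tz)

  lesion_masks <- list()
  taken <- array(FALSE, sh)
  for (li in seq_along(cfg$lesions)) {
    l <- cfg$lesions[[li]]
    d2 <- (an$X - l$center_mm[1])^2 + (an$Y - l$center_mm[2])^2 +
      (an$Z - l$center_mm[3])^2
    lm <- d2 <= l$radius_mm^2
    if (!any(lm)) stop("lesion ", li, " covers no voxel")
    if (any(lm & !an$prostate)) stop("lesion ", li, " extends outside the prostate")
    zone_mask <- if (l$zone == "PZ") an$pz else an$tz
    cvox <- round(l$center_mm / cfg$spacing + 0.5)
    if (!zone_mask[cvox[1], cvox[2], cvox[3]]) {
      stop("lesion ", li, " center is not inside its declared zone (", l$zone, ")")
    }
    if (any(lm & taken)) stop("lesions overlap")
    taken <- taken | lm
    tissue_list[[4L + li]] <- lesion_preset_for_grade(l$grade, kin)
    tid[lm] <- 4L + li
    lesion_masks[[li]] <- mask_volume(lm, "ROI")
  }

  curves <- t(vapply(tissue_list, kinetic_curve, numeric(length(cfg$grid$times)),
                     grid = cfg$grid))
  # pre-contrast frames carry baseline only, whatever the onset time
  curves[, seq_len(cfg$grid$n_pre)] <-
    vapply(tissue_list, function(p) p$s0, numeric(1))

  Tn <- length(cfg$grid$times)
  clean <- array(curves[as.vector(tid), ], c(sh, Tn))
  if (cfg$partial_volume) clean <- blur_inplane(clean)

  set.seed(cfg$seed)
  data <- clean
  if (cfg$noise$sigma > 0) {
    n <- length(clean)
    if (cfg$noise$model == "gaussian") {
      data <- pmax(clean + stats::rnorm(n, 0, cfg$noise$sigma), 0)
    } else {
      data <- sqrt((clean + stats::rnorm(n, 0, cfg$noise$sigma))^2 +
                     stats::rnorm(n, 0, cfg$noise$sigma)^2)
    }
    dim(data) <- c(sh, Tn)
  }

  series <- dce_series(data, spacing = cfg$spacing, grid = cfg$grid)
  transforms <- NULL
  if (!is.null(cfg$motion)) {
    series <- inject_motion(series, cfg$motion)
    transforms <- cfg$motion
  }

  truth <- list(
    prostate = mask_volume(an$prostate, "prostate"),
    pz = mask_volume(an$pz, "PZ"),
    tz = mask_volume(an$tz, "TZ"),
    gm = mask_volume(an$gm, "GM"),
    lesion_masks = lesion_masks,
    lesion_kinetics = lapply(seq_along(cfg$lesions),
                             function(i) tissue_list[[4L + i]]),
    lesion_grades = vapply(cfg$lesions, function(l) as.character(l$grade), ""),
    transforms = transforms,
    tissue_id = tid,
    tissue_curves = curves,
    config = cfg
  )
  list(series = series, truth = truth)
}

#' Inject rigid in-plane motion into a dynamic series
#'
#' Resamples each frame after the first through its [affine2d()] transform
#' (linear interpolation, frame-minimum fill), providing ground truth for
#' motion-correction tests. The first frame is the fixed reference.
#'
#' @param series A [dce_series()].
#' @param transforms List of [affine2d()], one per frame after the first.
#' @return The series with motion applied.
#' @export
inject_motion <- function(series, transforms) {
  stopifnot(inherits(series, "dce_series"))
  Tn <- dim(series$data)[4]
  if (length(transforms) != Tn - 1L) {
    stop("need one transform per frame after the first (", Tn - 1L, ")")
  }
  out <- series$data
  for (j in seq_len(Tn - 1L)) {
    tf <- transforms[[j]]
    if (is.null(tf) || is_identity_affine(tf)) next
    out[, , , j + 1L] <- resample_frame(series$data[, , , j + 1L], tf)
  }
  dce_series(out, spacing = series$spacing, grid = series$grid)
}

#' Write a phantom to disk
#'
#' Writes `series.nii.gz` (+ time-grid sidecar), one NIfTI per ground-truth
#' mask under `masks/`, and `truth.json` with lesion kinetics, grades and
#' injected transforms.
#'
#' @param ph Result of [make_phantom()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(ph, dir) {
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  write_series(ph$series, file.path(dir, "series.nii.gz"))
  sp <- ph$series$spacing
  write_mask(ph$truth$prostate, file.path(dir, "masks", "prostate.nii.gz"), sp)
  write_mask(ph$truth$pz, file.path(dir, "masks", "pz.nii.gz"), sp)
  write_mask(ph$truth$gm, file.path(dir, "masks", "gm.nii.gz"), sp)
  for (i in seq_along(ph$truth$lesion_masks)) {
    write_mask(ph$truth$lesion_masks[[i]],
               file.path(dir, "masks", sprintf("lesion_%02d.nii.gz", i)), sp)
  }
  tf_json <- NULL
  if (!is.null(ph$truth$transforms)) {
    tf_json <- lapply(ph$truth$transforms, function(tf) {
      if (is.null(tf)) NULL else tf[c("tx", "ty", "rot", "scale")]
    })
  }
  jsonlite::write_json(
    list(lesion_grades = ph$truth$lesion_grades,
         lesion_kinetics = lapply(ph$truth$lesion_kinetics, unclass),
         transforms = tf_json,
         seed = ph$truth$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
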