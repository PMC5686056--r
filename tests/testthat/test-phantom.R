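test_that("kinetic curves follow the difference-of-exponentials form", {
  tg <- time_grid()
  flat <- tissue_kinetics(s0 = 50, A = 0, k1 = 0.02, k2 = 0.001, t0 = 30)
  expect_equal(kinetic_curve(flat, tg), rep(50, 12))
  # k2 = 0 plateau limit
  pl <- tissue_kinetics(s0 = 10, A = 100, k1 = 0.5, k2 = 0, t0 = 0)
  expect_equal(kinetic_curve(pl, c(0, 300, 600))[2:3], c(110, 110), tolerance = 1e-8)
  expect_error(tissue_kinetics(0, 1, 0.01, 0.02, 0), "k1 must exceed k2")
})

test_that("closed-form time-to-peak matches a dense-sampling argmax", {
  p <- tissue_kinetics(s0 = 0, A = 100, k1 = 0.05, k2 = 0.005, t0 = 0)
  tt <- seq(0, 2000, by = 1)
  dense <- kinetic_curve(p, tt)
  expect_equal(tt[which.max(dense)], log(0.05 / 0.005) / (0.05 - 0.005),
               tolerance = 1 / p$tau)  # 1 s sampling resolution
  expect_equal(p$tau, log(10) / 0.045)
})

test_that("phantom generation is deterministic and anatomically consistent", {
  ph1 <- snr20_phantom(seed = 5)
  ph2 <- snr20_phantom(seed = 5)
  expect_identical(ph1$series$data, ph2$series$data)
  ph3 <- snr20_phantom(seed = 6)
  expect_false(identical(ph1$series$data, ph3$series$data))
  expect_true(all(ph1$series$data >= 0))
  tr <- ph1$truth
  expect_true(all(tr$pz$data <= tr$prostate$data))
  expect_identical(tr$tz$data, tr$prostate$data & !tr$pz$data)
  expect_false(any(tr$gm$data & tr$prostate$data))
  expect_true(all(tr$lesion_masks[[1]]$data <= tr$pz$data))
})

test_that("noiseless sharp-boundary phantom voxels carry their tissue curve", {
  ph <- make_phantom(phantom_config(lesions = list(), partial_volume = FALSE))
  tg <- ph$series$grid
  kin <- kinetics_presets()
  pz_vox <- which(ph$truth$pz$data, arr.ind = TRUE)[1, ]
  tz_vox <- which(ph$truth$tz$data, arr.ind = TRUE)[1, ]
  pz_expect <- kinetic_curve(kin$benign_pz, tg); pz_expect[1:2] <- kin$benign_pz$s0
  tz_expect <- kinetic_curve(kin$benign_tz, tg); tz_expect[1:2] <- kin$benign_tz$s0
  expect_equal(as.numeric(ph$series$data[pz_vox[1], pz_vox[2], pz_vox[3], ]),
               pz_expect)
  expect_equal(as.numeric(ph$series$data[tz_vox[1], tz_vox[2], tz_vox[3], ]),
               tz_expect)
})

test_that("lesion mask volume matches the sphere volume to a voxel shell", {
  ph <- make_phantom(phantom_config())
  vol <- volume_cc(ph$truth$lesion_masks[[1]], ph$series$spacing)
  r <- 6.2
  analytic <- 4 / 3 * pi * r^3 / 1000
  # one-voxel-shell bound on the voxelization error
  shell <- 4 * pi * r^2 * max(c(1.25, 1.25, 2.5)) / 1000
  expect_lt(abs(vol - analytic), shell)
})

test_that("invalid lesion placements are rejected", {
  expect_error(make_phantom(phantom_config(
    lesions = list(list(center_mm = c(10, 10, 16.25), radius_mm = 5,
                        zone = "PZ", grade = "6")))),
    "outside the prostate")
  expect_error(make_phantom(phantom_config(
    lesions = list(list(center_mm = c(40, 52, 16.25), radius_mm = 6,
                        zone = "PZ", grade = "8"),
                   list(center_mm = c(40, 54, 16.25), radius_mm = 6,
                        zone = "PZ", grade = "6")))),
    "overlap")
  # TZ-declared center in PZ territory
  expect_error(make_phantom(phantom_config(
    lesions = list(list(center_mm = c(40, 53, 16.25), radius_mm = 5,
                        zone = "TZ", grade = "6")))),
    "declared zone")
})

test_that("graded lesion kinetics are strictly monotone in grade", {
  kin <- kinetics_presets()
  tt <- seq(0, 330, by = 1)
  grades <- c("lesion_g6", "lesion_g34", "lesion_g43", "lesion_g8")
  wi <- wo <- numeric(0)
  for (g in grades) {
    p <- kin[[g]]
    s <- kinetic_curve(p, tt) - p$s0
    wi <- c(wi, (p$sm - p$s0) / p$tau)
    wo <- c(wo, -(s[331] - s[271]) / 60)
  }
  expect_true(all(diff(wi) > 0))
  expect_true(all(diff(wo) > 0))
  # muscle is the slowest, lowest enhancer
  amps <- vapply(kin[c("muscle", "benign_pz", "benign_tz", grades)],
                 function(p) p$sm - p$s0, numeric(1))
  expect_true(all(amps[1] < amps[-1]))
})

test_that("rician noise keeps the sample mean near the rician mean", {
  sigma <- 8
  cfg <- phantom_config(lesions = list(),
                        noise = list(model = "rician", sigma = sigma), seed = 2)
  ph <- make_phantom(cfg)
  # a far corner of the grid: constant background 80, untouched by the
  # partial-volume blur around the anatomy
  vals <- ph$series$data[1:10, 1:10, , ]
  s <- 80
  # Rician mean via the Laguerre polynomial expression
  x <- -s^2 / (2 * sigma^2)
  l_half <- exp(x / 2) * ((1 - x) * besselI(-x / 2, 0) - x * besselI(-x / 2, 1))
  rice_mean <- sigma * sqrt(pi / 2) * l_half
  expect_lt(abs(mean(vals) - rice_mean), 3 * sigma / sqrt(length(vals)))
})

test_that("injected motion resamples exactly for integer shifts and inverts", {
  ph <- make_phantom(phantom_config(seed = 3))
  Tn <- dim(ph$series$data)[4]
  ident <- lapply(seq_len(Tn - 1), function(i) affine2d())
  expect_identical(inject_motion(ph$series, ident)$data, ph$series$data)
  tfs <- ident; tfs[[4]] <- affine2d(tx = 2, ty = 0)
  moved <- inject_motion(ph$series, tfs)
  f <- ph$series$data[, , , 5]; g <- moved$data[, , , 5]
  expect_equal(g[1:62, , ], f[3:64, , ])  # frame5(x) = frame5_orig(x + 2)
  # shift then inverse-shift recovers the interior to interpolation accuracy
  tf <- affine2d(tx = 1.3, ty = -0.7)
  fwd <- resample_frame(f, tf)
  back <- resample_frame(fwd, invert_affine(tf))
  core <- 4:61
  expect_lt(max(abs(back[core, core, ] - f[core, core, ])),
            0.05 * max(f))
})

test_that("phantoms write to disk as NIfTI plus JSON truth", {
  dir <- file.path(tempdir(), "ph_out")
  ph <- make_phantom(phantom_config(seed = 9))
  write_phantom(ph, dir)
  expect_true(file.exists(file.path(dir, "series.nii.gz")))
  expect_true(file.exists(file.path(dir, "masks", "prostate.nii.gz")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  s2 <- read_series(file.path(dir, "series.nii.gz"))
  expect_equal(as.numeric(s2$data), as.numeric(ph$series$data))
  m2 <- read_mask(file.path(dir, "masks", "prostate.nii.gz"), "prostate")
  expect_identical(m2$data, ph$truth$prostate$data)
})
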