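# brute-force between-class-variance search over the same 256-bin histogram,
# written independently of the implementation
otsu_oracle <- function(values, n_bins = 256) {
  edges <- seq(min(values), max(values), length.out = n_bins + 1)
  h <- tabulate(pmin(findInterval(values, edges, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  best <- -Inf; best_edge <- NA
  for (cut in 1:(n_bins - 1)) {
    lo <- 1:cut; hi <- (cut + 1):n_bins
    n0 <- sum(h[lo]); n1 <- sum(h[hi])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(h[lo] * centers[lo]) / n0
    mu1 <- sum(h[hi] * centers[hi]) / n1
    bc <- n0 * n1 * (mu0 - mu1)^2
    if (bc > best) { best <- bc; best_edge <- edges[cut + 1] }
  }
  best_edge
}

test_that("otsu threshold separates bimodal data and matches brute force", {
  v <- c(rep(0, 50), rep(10, 50))
  thr <- otsu_threshold(v)
  expect_gt(thr, 0); expect_lt(thr, 10)
  expect_error(otsu_threshold(rep(3, 10)), "distinct")
  # two distinct values split
  thr2 <- otsu_threshold(c(1, 2))
  expect_gt(thr2, 1); expect_lt(thr2, 2)
  set.seed(42)
  for (i in 1:5) {
    v <- c(rnorm(500, 0, 1), rnorm(500, 6 + i, 1.5))
    expect_equal(otsu_threshold(v), otsu_oracle(v), tolerance = 1e-12)
  }
})

# minimal nmf_result carrying explicit weights on a tiny grid
fake_nmf <- function(W, dim3 = c(nrow(W), 1L, 1L)) {
  structure(list(W = W, S = matrix(1, ncol(W), 12), k = ncol(W),
                 residual = 0, wp_index = 1L,
                 W_wp = { a <- array(0, dim3); a[seq_len(nrow(W))] <- W[, 1]; a },
                 voxels = seq_len(nrow(W)), dim3 = dim3, grid = time_grid()),
            class = "nmf_result")
}

test_that("purity segmentation uses a strict per-voxel weight fraction", {
  W <- rbind(c(0.7, 0.2, 0.1),   # 70% > 60 -> in
             c(0.6, 0.4, 0.0),   # exactly 60% -> out (strict)
             c(0.0, 0.0, 0.0))   # zero total weight -> out
  m <- purity_segment(fake_nmf(W), 60)
  expect_identical(as.vector(m$data), c(TRUE, FALSE, FALSE))
  expect_error(purity_segment(fake_nmf(W), 0), "beta")
})

test_that("pure-pattern voxels segment exactly for any purity threshold", {
  fx <- exact_factorization_fixture()
  r <- select_wp(run_nmf(fx$cm, 3))
  # recovered pattern order is a permutation: map wp back to the true group
  true_col <- which.max(apply(fx$S0, 1, cosine_sim, b = r$S[r$wp_index, ]))
  truth <- fx$W0[, true_col] > 0
  for (beta in c(40, 60, 99)) {
    m <- purity_segment(r, beta)
    expect_identical(as.vector(m$data[r$voxels]), as.vector(truth))
  }
})

test_that("purity segmentation is antitone in beta", {
  ph <- snr20_phantom(seed = 2)
  cm <- build_curve_matrix(ph$series, ph$truth$prostate)
  r <- select_wp(suppressWarnings(run_nmf(cm, 3)))
  m40 <- purity_segment(r, 40); m50 <- purity_segment(r, 50)
  m60 <- purity_segment(r, 60); m70 <- purity_segment(r, 70)
  expect_true(all(m70$data <= m60$data))
  expect_true(all(m60$data <= m50$data))
  expect_true(all(m50$data <= m40$data))
})

test_that("component cleanup removes sub-threshold islands only", {
  m <- array(FALSE, c(20, 20, 4))
  m[2:4, 2:4, 1:2] <- TRUE            # 18 voxels, 0.0703 cc: kept
  m[10:13, 10:12, 1] <- TRUE          # 12 voxels, 0.0469 cc: removed
  m[16:19, 16:18, 3] <- TRUE; m[16, 19, 3] <- TRUE  # 13 voxels, 0.0508 cc: kept
  out <- cleanup_components(mask_volume(m, "ROI"), 0.05, c(1.25, 1.25, 2.5))
  expect_true(all(out$data[2:4, 2:4, 1:2]))
  expect_false(any(out$data[10:13, 10:12, 1]))
  expect_true(all(out$data[16:19, 16:18, 3]))
  # never grows, idempotent, empty-safe
  expect_true(all(out$data <= m))
  expect_identical(cleanup_components(out, 0.05)$data, out$data)
  e <- array(FALSE, c(5, 5, 2))
  expect_identical(cleanup_components(mask_volume(e, "ROI"), 0.05)$data, e)
})

test_that("26-connectivity joins diagonal neighbours across slices", {
  m <- array(FALSE, c(4, 4, 3))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE   # touch only diagonally in 3D
  lab <- label_components(m)
  expect_equal(max(lab), 1)
  m[4, 4, 3] <- TRUE                        # isolated
  expect_equal(max(label_components(m)), 2)
})

test_that("zone assignment and the volume gate follow the configured rules", {
  d <- c(20, 20, 8)
  roi <- array(FALSE, d); roi[1:10, 1:10, 1] <- TRUE    # 100 voxels
  pz <- array(FALSE, d); tz <- array(FALSE, d)
  pz[1:15, 1:15, ] <- TRUE; tz[16:20, , ] <- TRUE
  # 15 of 100 roi voxels in PZ
  roi2 <- array(FALSE, d); roi2[1:10, 1:10, 1] <- TRUE
  pz15 <- array(FALSE, d); pz15[1:15, 1, 1] <- TRUE
  tz15 <- array(FALSE, d); tz15[!pz15] <- TRUE
  r <- gate_and_assign(mask_volume(roi2, "ROI"), mask_volume(pz15, "PZ"),
                       mask_volume(tz15, "TZ"),
                       seg_config(pz_fraction = 10, min_roi_cc = 0.1))
  expect_equal(sum(roi2 & pz15) / sum(roi2), 0.1)       # exactly 10%
  expect_equal(r$zone, "TZ")                             # strict >
  pz16 <- pz15; pz16[1:10, 2, 1] <- TRUE                 # push overlap to 20%
  r2 <- gate_and_assign(mask_volume(roi2, "ROI"), mask_volume(pz16, "PZ"),
                        mask_volume(tz15, "TZ"),
                        seg_config(pz_fraction = 10, min_roi_cc = 0.1))
  expect_equal(r2$zone, "PZ")
  expect_identical(r2$pz_roi_wp$data, roi2)
  expect_false(any(r2$tz_roi_wp$data))
  expect_false(any(r2$nat_pz$data & roi2))
  # 0.4 cc ROI rejected at the 0.5 cc gate (1.25 x 1.25 x 2.5 mm voxels)
  roi04 <- array(FALSE, d); roi04[seq_len(102)] <- TRUE   # 0.3984 cc
  r3 <- gate_and_assign(mask_volume(roi04, "ROI"), mask_volume(pz15, "PZ"),
                        mask_volume(tz15, "TZ"), seg_config())
  expect_true(r3$rejected)
  expect_lt(r3$volume_cc, 0.5)
  # empty roi: rejected, zone undefined
  r4 <- gate_and_assign(mask_volume(array(FALSE, d), "ROI"),
                        mask_volume(pz15, "PZ"), mask_volume(tz15, "TZ"),
                        seg_config())
  expect_true(r4$rejected)
  expect_true(is.na(r4$zone))
})

test_that("phantom lesions segment with high overlap at the operating point", {
  ds <- vapply(1:3, function(sd) {
    ph <- snr20_phantom(seed = sd)
    cm <- build_curve_matrix(ph$series, ph$truth$prostate)
    r <- select_wp(suppressWarnings(run_nmf(cm, 3)))
    seg <- segment_wp(r, ph$truth$pz, ph$truth$tz, seg_config())
    dice_coef(seg$roi_wp$data, ph$truth$lesion_masks[[1]]$data)
  }, numeric(1))
  expect_true(all(ds >= 0.6))
})
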