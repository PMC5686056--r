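# Shared fixtures, built in code at test time.

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# default-conditions phantom at peak-enhancement SNR 20 (the study noise level)
snr20_phantom <- function(seed = 1, ...) {
  sigma <- sigma_for_snr(kinetics_presets()$lesion_g34, 20)
  make_phantom(phantom_config(noise = list(model = "gaussian", sigma = sigma),
                              seed = seed, ...))
}

# true lesion enhancement curve as the factorization sees it (baseline
# removed, pre-contrast frames flat)
true_lesion_curve <- function(ph) {
  p <- ph$truth$lesion_kinetics[[1]]
  v <- kinetic_curve(p, ph$series$grid) - p$s0
  v[seq_len(ph$series$grid$n_pre)] <- 0
  v
}

# Exactly factorizable curve matrix: three voxel groups with disjoint
# temporal bumps (the factorization is then unique up to permutation/scale).
exact_factorization_fixture <- function(n_per_group = 80, seed = 7) {
  set.seed(seed)
  tg <- time_grid()
  S0 <- rbind(c(0, 0, 1, 3, 2, 0, 0, 0, 0, 0, 0, 0),
              c(0, 0, 0, 0, 0, 2, 4, 3, 0, 0, 0, 0),
              c(0, 0, 0, 0, 0, 0, 0, 0, 1, 2, 3, 2))
  P <- 3 * n_per_group
  W0 <- matrix(0, P, 3)
  for (g in 1:3) {
    W0[(g - 1) * n_per_group + seq_len(n_per_group), g] <- runif(n_per_group, 0.5, 2)
  }
  D <- W0 %*% S0
  cm <- structure(list(D = D, voxels = seq_len(P), dim3 = c(P, 1L, 1L),
                       grid = tg), class = "curve_matrix")
  list(cm = cm, W0 = W0, S0 = S0, grid = tg)
}

# independent permutation enumerator for exact-p oracles (recursive,
# distinct from the implementation's iterative builder)
perm_list <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perm_list(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# series wrapper around a plain 4D array with the default grid
quick_series <- function(arr, n_pre = 2) {
  dce_series(arr, spacing = c(1.25, 1.25, 2.5),
             grid = time_grid(seq(0, by = 30, length.out = dim(arr)[4]),
                              n_pre = n_pre))
}
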