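#' Build the baseline-corrected curve matrix of the prostate
#'
#' Extracts the signal-time curve of every prostate voxel, subtracts each
#' voxel's pre-contrast mean (the first `n_pre` frames of the time grid) and
#' clips negatives to zero, yielding the non-negative data matrix that the
#' factorization operates on.
#'
#' @param series A [dce_series()].
#' @param prostate Prostate [mask_volume()] on the series grid.
#' @return An object of class `curve_matrix`: list with `D` (voxels x
#'   frames), `voxels` (linear voxel indices into the 3D grid), `dim3`
#'   (spatial grid dimensions) and `grid` (the [time_grid()]).
#' @export
build_curve_matrix <- function(series, prostate) {
  stopifnot(inherits(series, "dce_series"))
  m <- as_mask_data(prostate)
  d <- dim(series$data)
  if (!identical(dim(m), d[1:3])) stop("mask is on a different grid")
  vox <- which(m)
  if (length(vox) == 0L) stop("empty prostate mask")
  nxyz <- prod(d[1:3])
  flat <- matrix(series$data, nrow = nxyz, ncol = d[4])
  D <- flat[vox, , drop = FALSE]
  n_pre <- series$grid$n_pre
  base <- rowMeans(D[, seq_len(n_pre), drop = FALSE])
  D <- pmax(D - base, 0)
  structure(list(D = D, voxels = vox, dim3 = d[1:3], grid = series$grid),
            class = "curve_matrix")
}

#' @export
print.curve_matrix <- function(x, ...) {
  cat(sprintf("<curve_matrix> %d voxels x %d frames\n", nrow(x$D), ncol(x$D)))
  invisible(x)
}

#' Estimate the number of temporal components
#'
#' Rank estimate from the PCA eigenspectrum of the curve matrix using the
#' Malinowski factor-indicator function: for candidate rank `n` the
#' indicator is `RE(n) / (T - n)^2` with `RE(n)` the real error computed
#' from the discarded eigenvalues; the estimated rank minimizes the
#' indicator. The result is clamped to `[2, 5]`; the pipeline default is a
#' fixed rank of 3, with this estimator available as an alternative.
#'
#' @param cm A [curve_matrix()].
#' @return Integer rank in 2..5.
#' @export
estimate_k <- function(cm) {
  D <- cm$D
  Tn <- ncol(D)
  if (nrow(D) <= Tn) stop("need more voxels than frames for rank estimation")
  ev <- eigen(crossprod(D), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  ev[ev < ev[1] * 1e-12] <- 0   # numerical-noise floor so exact ranks resolve
  if (sum(ev) <= 0 || ev[2] <= ev[1] * 1e-12) {
    warning("curve matrix is (near) rank deficient; returning k = 2")
    return(2L)
  }
  ind <- vapply(seq_len(Tn - 1L), function(n) {
    re <- sqrt(sum(ev[(n + 1):Tn]) / (nrow(D) * (Tn - n)))
    re / (Tn - n)^2
  }, numeric(1))
  k <- which.min(ind)
  if (k < 2L) {
    warning("indicator minimum below 2 components; clamping to k = 2")
    k <- 2L
  }
  if (k > 5L) {
    warning("indicator minimum above 5 components; clamping to k = 5")
    k <- 5L
  }
  as.integer(k)
}

# Deterministic NNDSVD-style initialization (zeros lifted to a small
# positive value so no entry starts locked at the boundary).
nndsvd_init <- function(D, k) {
  sv <- svd(D, nu = k, nv = k)
  P <- nrow(D); Tn <- ncol(D)
  W <- matrix(0, P, k); S <- matrix(0, k, Tn)
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  S[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k > 1) for (j in 2:k) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (npos >= nneg && npos > 0) {
      W[, j] <- sqrt(sv$d[j] * npos) * up / sqrt(sum(up^2))
      S[j, ] <- sqrt(sv$d[j] * npos) * vp / sqrt(sum(vp^2))
    } else if (nneg > 0) {
      W[, j] <- sqrt(sv$d[j] * nneg) * un / sqrt(sum(un^2))
      S[j, ] <- sqrt(sv$d[j] * nneg) * vn / sqrt(sum(vn^2))
    }
  }
  eps0 <- mean(D) * 1e-2
  W[W < eps0] <- eps0
  S[S < eps0] <- eps0
  list(W = W, S = S)
}

#' Non-negative matrix factorization of the curve matrix
#'
#' Factorizes `D ~ W %*% S` (voxels x patterns times patterns x frames)
#' under elementwise non-negativity by hierarchical alternating least
#' squares (HALS) block-coordinate descent on the Frobenius loss, from a
#' deterministic NNDSVD-style initialization. The loss is non-increasing
#' across iterations. Patterns are normalized to unit maximum with weights
#' rescaled so the product is unchanged; weight maps therefore stay in
#' intensity units.
#'
#' @param cm A [curve_matrix()].
#' @param k Number of patterns, `>= 2`. Default 3.
#' @param seed Seed, used only when `init = "random"`.
#' @param init `"nndsvd"` (default, deterministic) or `"random"`.
#' @param tol Relative residual-change convergence tolerance.
#' @param max_iter Maximum HALS iterations.
#' @return An object of class `nmf_result`: `W`, `S`, `k`, `residual`
#'   (relative Frobenius residual), `iterations`, `converged`, plus the
#'   voxel bookkeeping of the input. `wp_index` and `W_wp` are filled by
#'   [select_wp()].
#' @export
run_nmf <- function(cm, k = 3L, seed = 1L, init = c("nndsvd", "random"),
                    tol = 1e-6, max_iter = 4000L) {
  init <- match.arg(init)
  D <- cm$D
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  normD <- sqrt(sum(D^2))
  if (normD == 0) {
    W <- matrix(0, nrow(D), k); S <- matrix(0, k, ncol(D))
    res <- structure(list(W = W, S = S, k = k, residual = 0, iterations = 0L,
                          converged = TRUE, wp_index = NA_integer_, W_wp = NULL,
                          voxels = cm$voxels, dim3 = cm$dim3, grid = cm$grid),
                     class = "nmf_result")
    return(res)
  }
  if (init == "nndsvd") {
    ini <- nndsvd_init(D, k)
  } else {
    set.seed(seed)
    ini <- list(W = matrix(stats::runif(nrow(D) * k, 0, max(D)), ncol = k),
                S = matrix(stats::runif(k * ncol(D)), nrow = k))
  }
  W <- ini$W; S <- ini$S
  eps <- .Machine$double.eps
  prev <- Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    # HALS sweeps: one pass over pattern rows of S, then weight columns of W
    WtD <- crossprod(W, D); WtW <- crossprod(W)
    for (j in seq_len(k)) {
      num <- WtD[j, ] - WtW[j, ] %*% S + WtW[j, j] * S[j, ]
      S[j, ] <- pmax(num / max(WtW[j, j], eps), 0)
    }
    DSt <- D %*% t(S); SSt <- tcrossprod(S)
    for (j in seq_len(k)) {
      num <- DSt[, j] - W %*% SSt[, j] + SSt[j, j] * W[, j]
      W[, j] <- pmax(num / max(SSt[j, j], eps), 0)
    }
    if (it %% 10L == 0L || it == max_iter) {
      res <- sqrt(sum((D - W %*% S)^2)) / normD
      if (res < tol ||
          (is.finite(prev) && abs(prev - res) < tol * max(res, eps))) {
        converged <- TRUE
        prev <- res
        break
      }
      prev <- res
    }
  }
  if (!converged) {
    warning("NMF did not converge in ", max_iter, " iterations; returning best iterate")
  }
  # unit-maximum pattern normalization, weights rescaled to compensate
  sc <- apply(S, 1, max)
  sc[sc <= 0] <- 1
  S <- S / sc
  W <- W * rep(sc, each = nrow(W))
  structure(list(W = W, S = S, k = k,
                 residual = sqrt(sum((D - W %*% S)^2)) / normD,
                 iterations = it, converged = converged,
                 wp_index = NA_integer_, W_wp = NULL,
                 voxels = cm$voxels, dim3 = cm$dim3, grid = cm$grid),
            class = "nmf_result")
}

#' @export
print.nmf_result <- function(x, ...) {
  cat(sprintf("<nmf_result> k = %d, %d voxels, relative residual %.3g%s\n",
              x$k, nrow(x$W), x$residual,
              if (!is.na(x$wp_index)) sprintf(", wp pattern %d", x$wp_index) else ""))
  invisible(x)
}

#' Early area under a temporal pattern
#'
#' Trapezoidal area of each pattern over the early window `[0, t_max]`
#' seconds, integrating only over frames at or before `t_max` (no
#' extrapolation when `t_max` falls between frames).
#'
#' @param S Patterns matrix (k x frames) or a single pattern vector.
#' @param grid A [time_grid()].
#' @param t_max Upper limit of the early window in seconds. Default 90.
#' @return Numeric vector of areas, one per pattern.
#' @export
pattern_auc_early <- function(S, grid, t_max = 90) {
  if (is.null(dim(S))) S <- matrix(S, nrow = 1)
  times <- grid$times
  sel <- times <= t_max + 1e-9
  if (sum(sel) < 2L) stop("fewer than 2 frames inside the early window")
  tt <- times[sel]
  apply(S[, sel, drop = FALSE], 1, function(v) {
    sum(diff(tt) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
  })
}

#' Select the well-perfused pattern
#'
#' The well-perfused pattern is the factorized temporal signature with the
#' largest early (0-90 s) area under the curve. Ties are broken toward the
#' lowest pattern index with a warning. Fills `wp_index` and the 3D weight
#' map `W_wp` of the selected pattern.
#'
#' @param nmf An [run_nmf()] result.
#' @param grid A [time_grid()]; defaults to the grid stored in `nmf`.
#' @param t_max Early-window upper limit in seconds.
#' @return The `nmf_result` with `wp_index`, `W_wp` (3D array, zero outside
#'   the prostate) and `auc_early` (per-pattern areas) set.
#' @export
select_wp <- function(nmf, grid = NULL, t_max = 90) {
  stopifnot(inherits(nmf, "nmf_result"))
  if (is.null(grid)) grid <- nmf$grid
  auc <- pattern_auc_early(nmf$S, grid, t_max)
  best <- max(auc)
  hits <- which(abs(auc - best) <= 1e-12 * max(1, abs(best)))
  if (length(hits) > 1L) {
    warning("tie in early-AUC pattern selection; choosing the lowest index")
  }
  wp <- hits[1]
  W_wp <- array(0, nmf$dim3)
  W_wp[nmf$voxels] <- nmf$W[, wp]
  nmf$wp_index <- as.integer(wp)
  nmf$W_wp <- W_wp
  nmf$auc_early <- auc
  nmf
}

#' Save / load a factorization result
#'
#' The factorization bundle is stored as plain text: `W.csv`, `S.csv`,
#' `voxels.csv` and a `meta.json` carrying rank, selected pattern, grid and
#' dimensions — standard formats rather than a private binary.
#'
#' @param nmf An `nmf_result`.
#' @param dir Directory to write to / read from.
#' @return `write_nmf`: `dir` invisibly; `read_nmf`: the `nmf_result`.
#' @export
write_nmf <- function(nmf, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(nmf$W, file.path(dir, "W.csv"), row.names = FALSE)
  utils::write.csv(nmf$S, file.path(dir, "S.csv"), row.names = FALSE)
  utils::write.csv(data.frame(voxel = nmf$voxels), file.path(dir, "voxels.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(k = nmf$k, wp_index = nmf$wp_index,
                            residual = nmf$residual, dim3 = nmf$dim3,
                            times = nmf$grid$times, n_pre = nmf$grid$n_pre),
                       file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_nmf
#' @export
read_nmf <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  W <- as.matrix(utils::read.csv(file.path(dir, "W.csv")))
  S <- as.matrix(utils::read.csv(file.path(dir, "S.csv")))
  dimnames(W) <- NULL; dimnames(S) <- NULL
  voxels <- utils::read.csv(file.path(dir, "voxels.csv"))$voxel
  nmf <- structure(list(W = W, S = S, k = meta$k,
                        residual = meta$residual, iterations = NA_integer_,
                        converged = NA, wp_index = meta$wp_index, W_wp = NULL,
                        voxels = voxels, dim3 = meta$dim3,
                        grid = time_grid(meta$times, meta$n_pre)),
                   class = "nmf_result")
  if (!is.na(meta$wp_index) && !is.null(meta$wp_index)) {
    W_wp <- array(0, nmf$dim3)
    W_wp[nmf$voxels] <- nmf$W[, nmf$wp_index]
    nmf$W_wp <- W_wp
  }
  nmf
}
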