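#' Spearman rank correlation with ordinal groups
#'
#' Rank correlation with average ranks for ties. The p-value uses the
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of
#' freedom; for small samples an exact permutation p-value (enumerating
#' all orderings of `y`) is available.
#'
#' @param x Numeric values (e.g. a DCE score or ROI volume).
#' @param y Ordinal group codes (e.g. Gleason group 1..4).
#' @param exact Compute the exact permutation p-value; only for `n <= 10`.
#' @return List with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_assoc <- function(x, y, exact = FALSE) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in x or y")
  rho <- stats::cor(rank(x), rank(y))
  if (exact) {
    if (n > 10L) stop("exact permutation p only supported for n <= 10")
    perms <- permutations_of(n)
    rx <- rank(x); ry <- rank(y)
    obs <- abs(rho)
    count <- 0L
    for (i in seq_len(nrow(perms))) {
      r <- stats::cor(rx, ry[perms[i, ]])
      if (abs(r) >= obs - 1e-12) count <- count + 1L
    }
    p <- count / nrow(perms)
    method <- "exact permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

# all permutations of 1..n (n small), deterministic order
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      r <- r + 1L
      row <- append(sub[i, ], n, after = pos - 1L)
      out[r, ] <- row
    }
  }
  out
}

#' ROC area under the curve (Mann-Whitney)
#'
#' AUC for discriminating aggressive (positive class) from indolent cases,
#' computed as the Mann-Whitney U statistic with half-credit for ties:
#' the probability that a random aggressive case scores above a random
#' indolent one.
#'
#' @param scores Numeric scores.
#' @param labels Class labels; `positive` indicates the aggressive class.
#' @param positive Value of `labels` treated as positive. Default
#'   `"aggressive"`.
#' @return AUC in 0..1.
#' @export
roc_auc <- function(scores, labels, positive = "aggressive") {
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Segmentation-configuration sweep over a phantom cohort
#'
#' Re-runs [gate_and_assign()] over a grid of segmentation methods
#' (Otsu and the purity thresholds) crossed with PZ-fraction thresholds,
#' and reports per cell the Spearman correlation between the resulting
#' ROI volume and the Gleason group, along with the PZ/TZ/rejected counts.
#' Rejected cases keep their volume (0 when empty) for the correlation but
#' are counted as rejected.
#'
#' @param cases List of cases, each a list with `nmf` (an `nmf_result`
#'   with `wp_index`), `pz`, `tz` ([mask_volume()]s), `gs_group` (ordinal
#'   Gleason group code) and `spacing`.
#' @param methods Character vector from `"otsu"`, `"purity40"`,
#'   `"purity50"`, `"purity60"`, `"purity70"`.
#' @param pz_fractions Numeric vector from 10, 15, 20.
#' @return Data frame (class `sweep_report`) with one row per cell:
#'   `method`, `pz_fraction`, `rho`, `p_value`, `n_pz`, `n_tz`,
#'   `n_rejected`.
#' @export
sweep_segmentation <- function(cases,
                               methods = c("otsu", "purity40", "purity50",
                                           "purity60", "purity70"),
                               pz_fractions = c(10, 15, 20)) {
  grid <- expand.grid(method = methods, pz_fraction = pz_fractions,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    meth <- grid$method[g]; pf <- grid$pz_fraction[g]
    cfg <- if (meth == "otsu") seg_config("otsu", pz_fraction = pf)
           else seg_config("purity", beta = as.numeric(sub("purity", "", meth)),
                           pz_fraction = pf)
    vols <- numeric(length(cases)); zone <- character(length(cases))
    rej <- logical(length(cases))
    for (i in seq_along(cases)) {
      cs <- cases[[i]]
      seg <- segment_wp(cs$nmf, cs$pz, cs$tz, cfg, cs$spacing)
      vols[i] <- seg$volume_cc
      zone[i] <- ifelse(is.na(seg$zone), "none", seg$zone)
      rej[i] <- seg$rejected
    }
    gs <- vapply(cases, function(cs) cs$gs_group, numeric(1))
    sp <- tryCatch(spearman_assoc(vols, gs),
                   error = function(e) list(rho = NA_real_, p_value = NA_real_))
    data.frame(method = meth, pz_fraction = pf, rho = sp$rho,
               p_value = sp$p_value,
               n_pz = sum(zone == "PZ" & !rej), n_tz = sum(zone == "TZ" & !rej),
               n_rejected = sum(rej), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_report", class(out))
  out
}

#' Concordance between biopsy-level map means and usROI features
#'
#' Pearson correlation and least-squares slope between the feature values
#' computed from each biopsy's usROI curve and the mean of the
#' aggressiveness map over the biopsy region — the consistency check that
#' the map generalizes the region-level feature faithfully.
#'
#' @param biopsy_table Data frame from [score_biopsies()].
#' @param feature Feature column to use (e.g. `"early_aufc_ratio"`).
#' @return List with `r` (Pearson), `slope`, `intercept`, `n`.
#' @export
concordance <- function(biopsy_table, feature = "early_aufc_ratio") {
  col <- paste0(sub("_ratio$|_raw$", "", feature),
                if (grepl("_ratio$", feature)) "_ratio" else "_raw")
  if (!col %in% names(biopsy_table)) stop("feature column not found: ", col)
  keep <- !biopsy_table$empty_usroi & is.finite(biopsy_table[[col]]) &
    is.finite(biopsy_table$map_mean)
  x <- biopsy_table[[col]][keep]
  y <- biopsy_table$map_mean[keep]
  if (length(x) < 3L) stop("need at least 3 biopsies with non-empty usROI")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in features or map means")
  fit <- stats::lm.fit(cbind(1, x), y)
  list(r = stats::cor(x, y), slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]), n = length(x))
}

#' Group-difference tests for feature tables
#'
#' Pass-through to the standard Kruskal-Wallis rank-sum test for a
#' feature across Gleason groups (no bespoke implementation; this is a
#' convenience wrapper so cohort tables can be tested in one call).
#'
#' @param values Numeric feature values.
#' @param groups Group codes.
#' @return The `htest` object from [stats::kruskal.test()].
#' @export
group_difference_test <- function(values, groups) {
  stats::kruskal.test(values, factor(groups))
}
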