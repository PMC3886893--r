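#' Welch's t-test with Satterthwaite degrees of freedom
#'
#' Two-sample t-test for unequal variances:
#' `t = (mean_a - mean_b) / sqrt(v_a/n_a + v_b/n_b)` with the Satterthwaite
#' approximation for the degrees of freedom and a two-sided p-value.
#' A thin wrapper over [stats::t.test()] returning the bare numbers; when
#' both samples are constant with equal means the statistic is undefined and
#' all three values are `NA` (flagged, not an error).
#'
#' @param sample_a,sample_b numeric vectors with at least 2 finite values
#' @return list with `t`, `df`, `p`
#' @export
welch_t <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stop("both samples need n >= 2")
  }
  res <- tryCatch(
    stats::t.test(sample_a, sample_b, var.equal = FALSE),
    error = function(e) NULL
  )
  if (is.null(res)) return(list(t = NA_real_, df = NA_real_, p = NA_real_))
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Benjamini–Hochberg FDR rejection flags
#'
#' Step-up procedure: sort p-values ascending, find the largest `i` with
#' `p_(i) <= i * q / m`, and reject all hypotheses at or below it. `NA`
#' p-values are excluded from `m` and never rejected. The rejection set is
#' monotone in `q`.
#'
#' @param p_values numeric vector in \[0, 1\] (NA allowed)
#' @param q target false discovery rate in (0, 1)
#' @return logical vector of rejections, same length as `p_values`
#' @export
bh_fdr <- function(p_values, q) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  rej <- !is.na(adj) & adj <= q
  rej
}

#' Fisher r-to-z contrast of two correlation coefficients
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1 - 3) + 1/(n2 - 3))`, the
#' standard normal score for the difference between two independent
#' correlations. Used to ask whether one scenario's pattern of network
#' metrics resembles a reference scenario significantly more than another's.
#'
#' @param r1,r2 correlation coefficients, `|r| < 1`
#' @param n1,n2 sample sizes (> 3)
#' @return z-score (positive when `r1 > r2`)
#' @export
fisher_r_to_z_diff <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("need n > 3 for the r-to-z contrast")
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    warning("|r| = 1 gives an infinite transform")
  }
  (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
}

#' Ensemble comparison of empirical and surrogate simulations
#'
#' The comparison protocol for per-node metrics: runs on the empirical
#' network are Welch-compared against the runs of each surrogate
#' realization separately, and the resulting t-statistics, degrees of
#' freedom and p-values are averaged across realizations. FDR control is
#' then applied across nodes to the averaged p-values within this metric
#' family.
#'
#' @param empirical_runs numeric matrix, runs x nodes (column names = node
#'   labels), of one metric on the empirical network
#' @param surrogate_runs list of matrices, one per surrogate realization,
#'   each runs x nodes with the same columns
#' @param q FDR level, default 0.05
#' @return data frame with one row per node: `node`, `mean_empirical`,
#'   `mean_surrogate`, `mean_diff`, `avg_t`, `avg_df`, `avg_p`,
#'   `n_signif_realizations` (realizations with p < 0.05 before averaging),
#'   `q_significant`, `direction` (sign of the mean difference)
#' @export
compare_ensembles <- function(empirical_runs, surrogate_runs, q = 0.05) {
  empirical_runs <- as.matrix(empirical_runs)
  if (!is.list(surrogate_runs)) surrogate_runs <- list(surrogate_runs)
  if (nrow(empirical_runs) < 2L) stop("need >= 2 empirical runs")
  nodes <- colnames(empirical_runs)
  if (is.null(nodes)) nodes <- paste0("n", seq_len(ncol(empirical_runs)))
  R <- length(surrogate_runs)
  tmat <- dmat <- pmat <- matrix(NA_real_, R, length(nodes))
  for (r in seq_len(R)) {
    sur <- as.matrix(surrogate_runs[[r]])
    if (nrow(sur) < 2L) stop("need >= 2 runs per surrogate realization")
    if (ncol(sur) != length(nodes)) stop("mismatched node sets")
    if (!is.null(colnames(sur)) && !identical(colnames(sur), nodes)) {
      stop("mismatched node sets")
    }
    for (j in seq_along(nodes)) {
      w <- welch_t(empirical_runs[, j], sur[, j])
      tmat[r, j] <- w$t; dmat[r, j] <- w$df; pmat[r, j] <- w$p
    }
  }
  avg_p <- colMeans(pmat, na.rm = TRUE)
  mean_sur <- colMeans(do.call(rbind, lapply(surrogate_runs, as.matrix)))
  out <- data.frame(
    node = nodes,
    mean_empirical = colMeans(empirical_runs),
    mean_surrogate = mean_sur,
    mean_diff = colMeans(empirical_runs) - mean_sur,
    avg_t = colMeans(tmat, na.rm = TRUE),
    avg_df = colMeans(dmat, na.rm = TRUE),
    avg_p = avg_p,
    n_signif_realizations = colSums(pmat < 0.05, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  out$q_significant <- bh_fdr(out$avg_p, q)
  out$direction <- sign(out$mean_diff)
  rownames(out) <- NULL
  out
}
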