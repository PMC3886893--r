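#' Derive a child seed from a master seed
#'
#' Counter-based derivation so any single run of a sweep can be reproduced
#' independently of the others. Stays within 32-bit integer range.
#'
#' @param master master seed (integer)
#' @param counter non-negative run counter
#' @return integer seed
#' @export
derive_seed <- function(master, counter) {
  as.integer((as.double(master) %% 65521 * 32749 + counter * 7919 + 1) %%
               2147483629)
}

#' Run a full scenario: base network plus surrogate families
#'
#' Simulates the base network and degree-matched randomized
#' ([maslov_rewire()]) and latticized ([latticize()]) surrogate realizations
#' across a grid of arrival intensities, with `n_reps` independent runs per
#' network per intensity. Returns per-run network statistics, aggregated
#' curves per family, and (optionally) per-run node-level metrics for
#' [compare_ensembles()]. All seeds are derived from `seed` by counter, so
#' the full report is bit-reproducible.
#'
#' @param base_net a [directed_network()]
#' @param lambdas numeric vector of external arrival rates
#' @param n_reps simulation runs per network per lambda
#' @param config a [sim_config()] supplying `mu`, `buffer_size`, `t_end`,
#'   `t_transient` and `arrival_mode` (its `lambda` and `seed` are
#'   overridden per run)
#' @param n_randomized,n_latticized surrogate realization counts (0 = skip
#'   that family)
#' @param seed master seed
#' @param node_metrics also collect per-run per-node utilization, blocking
#'   and mean contents (needed for ensemble node comparisons)
#' @return list of class `scenario_report`: `runs` (long data frame:
#'   `family`, `realization` — 0 for the base network —, `lambda`, `rep`,
#'   `seed`, `mean_utilization`, `mean_blocking`, `throughput`,
#'   `mean_transit_time`), `curves` (grand means per family x lambda x
#'   metric, long format), and `node_runs` (when requested: long per-node
#'   table)
#' @export
run_scenario <- function(base_net, lambdas, n_reps, config,
                         n_randomized = 0L, n_latticized = 0L, seed = 1L,
                         node_metrics = FALSE) {
  if (n_reps < 1L || any(lambdas < 0)) stop("infeasible replication design")
  nets <- list(list(family = "base", realization = 0L, net = base_net))
  counter <- 0L
  for (r in seq_len(n_randomized)) {
    counter <- counter + 1L
    nets[[length(nets) + 1L]] <- list(
      family = "randomized", realization = r,
      net = maslov_rewire(base_net, seed = derive_seed(seed, counter)))
  }
  for (r in seq_len(n_latticized)) {
    counter <- counter + 1L
    nets[[length(nets) + 1L]] <- list(
      family = "latticized", realization = r,
      net = latticize(base_net, seed = derive_seed(seed, counter)))
  }
  runs <- list()
  node_runs <- list()
  for (entry in nets) {
    for (lam in lambdas) {
      for (rep_i in seq_len(n_reps)) {
        counter <- counter + 1L
        run_seed <- derive_seed(seed, counter)
        cfg <- sim_config(lambda = lam, mu = config$mu,
                          buffer_size = config$buffer_size,
                          t_end = config$t_end,
                          t_transient = config$t_transient,
                          seed = run_seed,
                          arrival_mode = config$arrival_mode)
        trace <- run_simulation(entry$net, cfg)
        st <- network_stats(trace)
        runs[[length(runs) + 1L]] <- data.frame(
          family = entry$family, realization = entry$realization,
          lambda = lam, rep = rep_i, seed = run_seed, st,
          stringsAsFactors = FALSE)
        if (node_metrics) {
          ns <- node_stats(trace)
          node_runs[[length(node_runs) + 1L]] <- data.frame(
            family = entry$family, realization = entry$realization,
            lambda = lam, rep = rep_i,
            ns[, c("node", "utilization", "blocking", "mean_contents")],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  runs <- do.call(rbind, runs)
  metrics <- c("mean_utilization", "mean_blocking", "throughput",
               "mean_transit_time")
  curves <- do.call(rbind, lapply(metrics, function(m) {
    agg <- stats::aggregate(runs[[m]],
                            by = list(family = runs$family,
                                      lambda = runs$lambda),
                            FUN = mean, na.rm = TRUE)
    data.frame(family = agg$family, lambda = agg$lambda, metric = m,
               value = agg$x, stringsAsFactors = FALSE)
  }))
  structure(
    list(runs = runs, curves = curves,
         node_runs = if (node_metrics) do.call(rbind, node_runs) else NULL,
         lambdas = lambdas, seed = seed),
    class = "scenario_report"
  )
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("scenario_report:", nrow(x$runs), "runs over",
      length(unique(x$runs$family)), "families and",
      length(x$lambdas), "intensities\n")
  invisible(x)
}

#' Similarity of scenario reports via correlated metric patterns
#'
#' Correlates the network-metric values (transit time, throughput,
#' utilization, blocking) across the shared (family x lambda) cells between
#' a reference report and each of two comparison reports, then contrasts the
#' two correlations with [fisher_r_to_z_diff()]. A positive z for a metric
#' means report `a` resembles the reference significantly more than report
#' `b` does.
#'
#' @param report_ref,report_a,report_b `scenario_report` objects sharing
#'   the same lambda grid and family set
#' @return data frame with one row per metric: `metric`, `r_ref_a`,
#'   `r_ref_b`, `n_cells`, `z`
#' @export
scenario_similarity <- function(report_ref, report_a, report_b) {
  key <- function(cv) paste(cv$family, cv$lambda, cv$metric)
  ref <- report_ref$curves
  a <- report_a$curves
  b <- report_b$curves
  if (!setequal(key(ref), key(a)) || !setequal(key(ref), key(b))) {
    stop("reports do not share the same family x lambda x metric grid")
  }
  a <- a[match(key(ref), key(a)), ]
  b <- b[match(key(ref), key(b)), ]
  metrics <- unique(ref$metric)
  out <- lapply(metrics, function(m) {
    i <- ref$metric == m & is.finite(ref$value) & is.finite(a$value) &
      is.finite(b$value)
    nc <- sum(i)
    ra <- stats::cor(ref$value[i], a$value[i])
    rb <- stats::cor(ref$value[i], b$value[i])
    z <- if (nc > 3 && abs(ra) < 1 && abs(rb) < 1) {
      fisher_r_to_z_diff(ra, nc, rb, nc)
    } else NA_real_
    data.frame(metric = m, r_ref_a = ra, r_ref_b = rb, n_cells = nc, z = z,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Parameter sweeps: buffer size or planted rich-club size
#'
#' `buffer_size`: re-runs the base scenario at each buffer capacity and
#' collects per-node statistics, to document that buffer capacity changes
#' results quantitatively but not qualitatively. `rich_club_size`: generates
#' a planted rich-club network ([rich_club_synthetic()]) per club size and
#' collects system-level curves.
#'
#' @param parameter `"buffer_size"` or `"rich_club_size"`
#' @param values vector of parameter values (e.g. buffers `c(2, 5, 10)` or
#'   club sizes `c(10, 20, 30)`)
#' @param base_net network for the buffer sweep (ignored for the rich-club
#'   sweep, which generates its own 100-node networks)
#' @param lambdas arrival intensities
#' @param n_reps runs per cell
#' @param config a [sim_config()] template
#' @param seed master seed
#' @return list of class `sweep_report`: `parameter`, `values`, `system`
#'   (long data frame of per-run network statistics with a `value` column
#'   for the swept parameter) and, for the buffer sweep, `node` (per-node
#'   statistics per value)
#' @export
sweep_parameter <- function(parameter = c("buffer_size", "rich_club_size"),
                            values, base_net = NULL, lambdas, n_reps,
                            config, seed = 1L) {
  parameter <- match.arg(parameter)
  system_rows <- list()
  node_rows <- list()
  for (vi in seq_along(values)) {
    v <- values[vi]
    sub_seed <- derive_seed(seed, 100000L + vi)
    if (parameter == "buffer_size") {
      stopifnot(!is.null(base_net))
      cfg <- sim_config(lambda = lambdas[1L], mu = config$mu,
                        buffer_size = v, t_end = config$t_end,
                        t_transient = config$t_transient,
                        arrival_mode = config$arrival_mode)
      rep_ <- run_scenario(base_net, lambdas, n_reps, cfg, seed = sub_seed,
                           node_metrics = TRUE)
      node_rows[[vi]] <- data.frame(value = v, rep_$node_runs,
                                    stringsAsFactors = FALSE)
    } else {
      net <- rich_club_synthetic(n = 100L, n_rc = v,
                                 seed = derive_seed(seed, 200000L + vi))
      rep_ <- run_scenario(net, lambdas, n_reps, config, seed = sub_seed)
    }
    system_rows[[vi]] <- data.frame(value = v, rep_$runs,
                                    stringsAsFactors = FALSE)
  }
  structure(
    list(parameter = parameter, values = values,
         system = do.call(rbind, system_rows),
         node = if (length(node_rows)) do.call(rbind, node_rows) else NULL),
    class = "sweep_report"
  )
}
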