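#' Restrict a trace to a post-transient window
#'
#' Returns the same trace with its statistics window set to `[t0, t_end]`.
#' All statistic functions then use only events inside the window: busy and
#' occupancy intervals are clipped to it (units alive across the boundary
#' contribute only their in-window occupancy), arrivals and ejections are
#' counted by event time, and delivered/dropped classification uses
#' `t_final >= t0`.
#'
#' @param trace a `sim_trace`
#' @param t0 warmup cutoff, `0 <= t0 < t_end` (`t0 = 0` gives full-trace
#'   statistics)
#' @return the trace with an updated `window`
#' @export
remove_transient <- function(trace, t0) {
  if (t0 < 0 || t0 >= trace$config$t_end) {
    stop("t0 must lie in [0, t_end)")
  }
  trace$window <- c(t0, trace$config$t_end)
  trace
}

overlap_len <- function(a, b, t0, t1) {
  pmax(0, pmin(b, t1) - pmax(a, t0))
}

#' Node-level congestion statistics
#'
#' For every node over the statistics window: `utilization`, the exact
#' time-weighted fraction of window time the server is busy; `blocking`, the
#' number of units ejected at the node divided by the number of units
#' arriving at it (reported as `NA`, not zero, when the node saw no
#' arrivals, so cross-node means are not biased); and `mean_contents`, the
#' time-average of the node contents X_i(t) = in-service + queued units,
#' computed by exact piecewise-constant integration. In- and out-degrees are
#' included for convenience.
#'
#' @param trace a `sim_trace`
#' @param window length-2 numeric window, default the trace's own
#' @return data frame with one row per node: `node`, `in_degree`,
#'   `out_degree`, `utilization`, `blocking`, `mean_contents`, `arrivals`,
#'   `ejections`
#' @export
node_stats <- function(trace, window = trace$window) {
  t0 <- window[1L]; t1 <- window[2L]
  if (t1 <= t0) stop("empty window")
  W <- t1 - t0
  n <- n_nodes(trace$net)
  seg <- trace$segments
  fnode <- factor(seg$node, levels = seq_len(n))
  end <- ifelse(is.na(seg$t_depart), t1, seg$t_depart)
  busy <- ifelse(is.na(seg$t_service_start), 0,
                 overlap_len(seg$t_service_start, end, t0, t1))
  contents <- overlap_len(seg$t_arrive, end, t0, t1)
  busy_by <- tapply(busy, fnode, sum, default = 0)
  cont_by <- tapply(contents, fnode, sum, default = 0)
  arr_in <- seg$t_arrive >= t0 & seg$t_arrive < t1
  arrivals <- as.integer(table(fnode[arr_in]))
  ejected <- is.na(seg$t_service_start) & !is.na(seg$t_depart) &
    seg$t_depart >= t0 & seg$t_depart < t1
  ejections <- as.integer(table(fnode[ejected]))
  d <- degrees(trace$net)
  data.frame(
    node = trace$net$nodes,
    in_degree = d$in_degree,
    out_degree = d$out_degree,
    utilization = as.numeric(busy_by) / W,
    blocking = ifelse(arrivals > 0, ejections / arrivals, NA_real_),
    mean_contents = as.numeric(cont_by) / W,
    arrivals = arrivals,
    ejections = ejections,
    stringsAsFactors = FALSE
  )
}

#' Per-edge throughput
#'
#' Counts unit traversals of every directed edge within the window (hop
#' times from [trace_hops()]). With a node membership from
#' [classify_nodes()], edges are additionally labelled rich/feeder/local and
#' per-class mean throughputs are attached as attribute `class_means`.
#'
#' @param trace a `sim_trace`
#' @param membership optional data frame from [classify_nodes()]
#' @param level club level for edge classification (see [classify_edges()])
#' @param window length-2 numeric window
#' @return data frame with one row per edge of the network: `source`,
#'   `target`, `throughput`, and `class` when membership is given. The
#'   column sum of `throughput` equals the number of in-window hops.
#' @export
edge_throughput <- function(trace, membership = NULL, level = "RC2",
                            window = trace$window) {
  t0 <- window[1L]; t1 <- window[2L]
  hops <- trace_hops(trace)
  hops <- hops[hops$t >= t0 & hops$t < t1, , drop = FALSE]
  el <- edge_labels(trace$net)
  key <- paste(trace$net$edges[, 1L], trace$net$edges[, 2L])
  cnt <- table(factor(paste(hops$from, hops$to), levels = key))
  out <- data.frame(el, throughput = as.integer(cnt),
                    stringsAsFactors = FALSE)
  if (!is.null(membership)) {
    cls <- classify_edges(trace$net, membership, level = level)
    out$class <- cls$class
    attr(out, "class_means") <- tapply(out$throughput, out$class, mean)
  }
  out
}

#' Network-level statistics
#'
#' Aggregates over the window: mean node utilization and blocking (blocking
#' averaged over nodes with at least one arrival), `throughput` (count of
#' units delivered to their destination), and `mean_transit_time` (mean of
#' `t_final - t_created` over delivered units, i.e. the total waiting plus
#' service time accumulated along the walk; dropped units are excluded).
#'
#' @inheritParams node_stats
#' @return one-row data frame: `mean_utilization`, `mean_blocking`,
#'   `throughput`, `mean_transit_time`, `created`, `dropped`
#' @export
network_stats <- function(trace, window = trace$window) {
  t0 <- window[1L]; t1 <- window[2L]
  ns <- node_stats(trace, window)
  u <- trace$units
  created <- sum(u$t_created >= t0 & u$t_created < t1)
  del <- u$status == "delivered" & !is.na(u$t_final) &
    u$t_final >= t0 & u$t_final < t1
  drp <- u$status == "dropped" & !is.na(u$t_final) &
    u$t_final >= t0 & u$t_final < t1
  transit <- u$t_final[del] - u$t_created[del]
  data.frame(
    mean_utilization = mean(ns$utilization),
    mean_blocking = mean(ns$blocking, na.rm = TRUE),
    throughput = sum(del),
    mean_transit_time = if (any(del)) mean(transit) else NA_real_,
    created = created,
    dropped = sum(drp)
  )
}

#' Path-level statistics
#'
#' Compiles all completed source-to-destination trajectories in the window
#' into per-pair delivery counts and mean transit times (delays), plus the
#' marginal means: for each source, the mean over destinations of the pair
#' values, and for each target, the mean over sources. Pairs with no
#' deliveries hold `NA` delay, never zero.
#'
#' @inheritParams node_stats
#' @return list with `deliveries` (n x n count matrix, rows = sources),
#'   `mean_delay` (n x n matrix), `by_source` and `by_target` (data frames
#'   with `mean_deliveries` and `mean_delay` marginals). The total of
#'   `deliveries` equals [network_stats()]`$throughput` on the same window.
#' @export
path_stats <- function(trace, window = trace$window) {
  t0 <- window[1L]; t1 <- window[2L]
  nodes <- trace$net$nodes
  n <- length(nodes)
  u <- trace$units
  del <- u$status == "delivered" & !is.na(u$t_final) &
    u$t_final >= t0 & u$t_final < t1
  src <- factor(u$source[del], levels = nodes)
  dst <- factor(u$destination[del], levels = nodes)
  transit <- u$t_final[del] - u$t_created[del]
  deliveries <- table(src, dst)
  delay <- tapply(transit, list(src, dst), mean)
  deliveries <- matrix(as.integer(deliveries), n, n,
                       dimnames = list(source = nodes, target = nodes))
  dimnames(delay) <- list(source = nodes, target = nodes)
  off <- row(deliveries) != col(deliveries)
  by_source <- data.frame(
    node = nodes,
    mean_deliveries = rowSums(deliveries) / (n - 1),
    mean_delay = vapply(seq_len(n), function(i)
      mean(delay[i, off[i, ]], na.rm = TRUE), numeric(1)),
    stringsAsFactors = FALSE
  )
  by_target <- data.frame(
    node = nodes,
    mean_deliveries = colSums(deliveries) / (n - 1),
    mean_delay = vapply(seq_len(n), function(j)
      mean(delay[off[, j], j], na.rm = TRUE), numeric(1)),
    stringsAsFactors = FALSE
  )
  list(deliveries = deliveries, mean_delay = delay,
       by_source = by_source, by_target = by_target)
}

#' Total network load time series N(t)
#'
#' Reconstructs the piecewise-constant total number of signal units in the
#' network (sum of all node contents; channel contents are identically zero
#' because hops are instantaneous, but belong to the same sum formally) from
#' unit lifetimes: +1 at each creation, -1 at each delivery or drop.
#'
#' @param trace a `sim_trace`
#' @return data frame with columns `time` and `N`; `N` is the load just
#'   after the event at `time`, starting from `(0, 0)`.
#' @export
load_series <- function(trace) {
  u <- trace$units
  t_up <- u$t_created
  t_dn <- u$t_final[!is.na(u$t_final)]
  times <- c(0, t_up, t_dn)
  delta <- c(0L, rep(1L, length(t_up)), rep(-1L, length(t_dn)))
  ord <- order(times, -delta)  # at ties, departures (-1) after arrivals
  data.frame(time = times[ord], N = cumsum(delta[ord]))
}

#' Linear interpolation onto a uniform grid
#'
#' Resamples an event-driven (non-uniformly sampled) series at
#' `t = t0, t0 + dt, ...` by linear interpolation between observed points,
#' reproducing the uniform-sampling preprocessing step used before
#' time-series analyses. Exact time-averages in this package use
#' piecewise-constant integration instead; interpolation is an approximation
#' whose error is bounded by the largest inter-event jump.
#'
#' @param series data frame with columns `time` and a value column (the
#'   second column is used)
#' @param dt sampling interval (> 0)
#' @return data frame with columns `time`, `value` on the uniform grid
#'   spanning the original support
#' @export
interpolate_uniform <- function(series, dt) {
  if (dt <= 0) stop("dt must be positive")
  if (nrow(series) == 0L) stop("empty series")
  tt <- series[[1L]]
  v <- series[[2L]]
  grid <- seq(tt[1L], tt[length(tt)], by = dt)
  out <- stats::approx(tt, v, xout = grid, method = "linear", ties = "ordered")
  data.frame(time = out$x, value = out$y)
}

#' Detect the warmup transient by the ensemble-average method
#'
#' Averages replicate load series point-wise on a common uniform grid and
#' returns the first grid time after which the ensemble mean stays within
#' `tolerance` (relative) of the long-run mean — estimated from the second
#' half of the horizon — for the remainder of the horizon. A series that
#' never stabilizes returns the horizon end with a warning.
#'
#' @param series_list list of >= 2 replicate data frames on a shared grid
#'   (columns `time`, value)
#' @param tolerance relative stabilization band, default 0.05
#' @return suggested warmup cutoff time
#' @export
detect_transient <- function(series_list, tolerance = 0.05) {
  if (length(series_list) < 2L) stop("need at least 2 replicate series")
  tt <- series_list[[1L]][[1L]]
  for (s in series_list[-1L]) {
    if (!isTRUE(all.equal(s[[1L]], tt))) stop("series grids differ")
  }
  m <- rowMeans(vapply(series_list, function(s) as.numeric(s[[2L]]),
                       numeric(length(tt))))
  second_half <- tt >= (tt[1L] + tt[length(tt)]) / 2
  M <- mean(m[second_half])
  ok <- abs(m - M) <= tolerance * abs(M)
  stable_from <- rev(cumprod(rev(ok))) > 0  # TRUE where all later points ok
  if (!any(stable_from)) {
    warning("ensemble mean never stabilizes within tolerance")
    return(tt[length(tt)])
  }
  tt[which(stable_from)[1L]]
}
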