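#' Simulation configuration
#'
#' Parameters of the discrete-event communication model. Rates are per
#' dimensionless time unit. `lambda` is the external arrival rate of new
#' signal units; in the default `"global"` mode it is a single network-wide
#' Poisson rate with uniformly random source nodes, while `"per_node"` mode
#' treats `lambda` as a per-node injection rate (equivalent to a global rate
#' of `lambda * n_nodes`). `mu` is the exponential service rate of every
#' node's server, fixed while `lambda` is varied to control load. `buffer_size`
#' (K) counts *queued* units only; the server slot is separate, so node
#' contents never exceed `K + 1`.
#'
#' @param lambda external arrival rate (>= 0)
#' @param mu service rate (> 0), default 1 (time is measured in mean service
#'   times)
#' @param buffer_size queue capacity K (>= 0), default 5
#' @param t_end simulation horizon, default 2e6 time units
#' @param t_transient warmup interval discarded by default from all
#'   statistics, default 4e4
#' @param seed integer RNG seed (required for reproducible traces)
#' @param arrival_mode `"global"` or `"per_node"`
#' @return object of class `sim_config`
#' @export
sim_config <- function(lambda, mu = 1, buffer_size = 5L, t_end = 2e6,
                       t_transient = 4e4, seed = NULL,
                       arrival_mode = c("global", "per_node")) {
  arrival_mode <- match.arg(arrival_mode)
  stopifnot(lambda >= 0, mu > 0, buffer_size >= 0,
            t_transient >= 0, t_transient < t_end)
  structure(
    list(lambda = lambda, mu = mu, buffer_size = as.integer(buffer_size),
         t_end = t_end, t_transient = t_transient, seed = seed,
         arrival_mode = arrival_mode),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: lambda=%g (%s), mu=%g, K=%d, t_end=%g, transient=%g, seed=%s\n",
    x$lambda, x$arrival_mode, x$mu, x$buffer_size, x$t_end, x$t_transient,
    if (is.null(x$seed)) "none" else format(x$seed)))
  invisible(x)
}

#' Run the discrete-event simulation
#'
#' Executes the communication model on a directed network: Poisson external
#' arrivals with uniform random (source, destination) pairs, exponential
#' single-server service at every node, non-preemptive LIFO queueing in a
#' finite push-out buffer (an arrival at a full queue ejects the oldest
#' queued unit), instantaneous hops to uniformly random out-neighbours, and
#' immediate absorption when a hop lands on the unit's destination. All
#' stochastic draws use inverse-transform sampling from a seeded uniform
#' stream, so a given (network, config, seed) yields a bit-identical trace.
#'
#' @param net a [directed_network()] passing the degree floor of
#'   [check_simulatable()] (every node needs an out-edge for routing)
#' @param config a [sim_config()]
#' @return object of class `sim_trace`: list with `units` (one row per
#'   signal unit: `uid`, `source`, `destination` as node labels,
#'   `t_created`, `status` in in_network/delivered/dropped, `t_final`),
#'   `segments` (one row per node visit: `uid`, `node` index, `t_arrive`,
#'   `t_service_start`, `t_depart`; service start is `NA` for units ejected
#'   while queued, departure is `NA` for units still present at `t_end`),
#'   `net`, `config`, and the default statistics `window`
#'   `c(t_transient, t_end)`.
#' @export
run_simulation <- function(net, config) {
  stopifnot(inherits(net, "directed_network"), inherits(config, "sim_config"))
  chk <- check_simulatable(net)
  if (!chk$ok) {
    stop("network violates the degree floor (in/out degree >= 1); offenders: ",
         paste(utils::head(chk$offenders$node, 5L), collapse = ", "))
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  rate_ext <- if (config$arrival_mode == "global") config$lambda else
    config$lambda * n_nodes(net)
  raw <- cpp_simulate(out_neighbours0(net), rate_ext, config$mu,
                      config$buffer_size, config$t_end)
  units <- raw$units
  units$source <- net$nodes[units$source]
  units$destination <- net$nodes[units$destination]
  units$status <- factor(
    c("in_network", "delivered", "dropped")[units$status + 1L],
    levels = c("in_network", "delivered", "dropped"))
  structure(
    list(units = units, segments = raw$segments, net = net, config = config,
         window = c(config$t_transient, config$t_end)),
    class = "sim_trace"
  )
}

#' @export
print.sim_trace <- function(x, ...) {
  tab <- table(x$units$status)
  cat(sprintf(
    "sim_trace: %d units (%d delivered, %d dropped, %d in network) over %g time units\n",
    nrow(x$units), tab[["delivered"]], tab[["dropped"]], tab[["in_network"]],
    x$config$t_end))
  invisible(x)
}

#' Hop table of a trace
#'
#' Reconstructs every hop (directed edge traversal) from the per-visit
#' segments: consecutive segments of the same unit give internal hops at the
#' departure instant, and each delivered unit contributes a final hop from
#' its last visited node to its destination at the delivery instant (the
#' destination itself has no segment because absorption happens on arrival,
#' before any queueing).
#'
#' @param trace a `sim_trace`
#' @return data frame with columns `uid`, `from`, `to` (node indices), `t`
#' @export
trace_hops <- function(trace) {
  seg <- trace$segments
  ord <- order(seg$uid, seg$t_arrive)
  uid <- seg$uid[ord]
  node <- seg$node[ord]
  dep <- seg$t_depart[ord]
  k <- length(uid)
  internal <- if (k > 1L) which(uid[-k] == uid[-1L]) else integer(0)
  hops <- data.frame(uid = uid[internal], from = node[internal],
                     to = node[internal + 1L], t = dep[internal])
  delivered <- trace$units$status == "delivered"
  if (any(delivered)) {
    u <- trace$units[delivered, ]
    last_node <- vapply(split(node, uid), function(v) v[length(v)],
                        integer(1))
    final <- data.frame(
      uid = u$uid,
      from = unname(last_node[as.character(u$uid)]),
      to = match(u$destination, trace$net$nodes),
      t = u$t_final)
    hops <- rbind(hops, final)
  }
  hops[order(hops$t), , drop = FALSE]
}
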