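#' Expected visit counts of the absorbing random walk
#'
#' For the uniform random walk on the directed network with absorption at
#' `destination`, returns the expected number of visits to each transient
#' node from each source, via the fundamental matrix of the absorbing chain:
#' `V = (I - Q)^{-1}` restricted to transient nodes, where `Q` is the
#' transition matrix among them. The starting visit at the source counts
#' (the unit arrives there when injected); the absorbing destination is
#' never counted, because a unit is removed on the hop that reaches it,
#' before any queueing. Sources that cannot reach the destination are
#' flagged with `NA` rows.
#'
#' @param net a [directed_network()]
#' @param destination node label (or index) of the absorbing node
#' @return matrix of expected visits, rows = source nodes, columns = visited
#'   nodes (both over all nodes; the destination column is zero, `NA` rows
#'   mark sources that cannot reach the destination)
#' @export
absorbing_visit_counts <- function(net, destination) {
  n <- n_nodes(net)
  d <- if (is.character(destination)) match(destination, net$nodes) else
    as.integer(destination)
  if (is.na(d) || d < 1L || d > n) stop("unknown destination node")
  outdeg <- tabulate(net$edges[, 1L], nbins = n)
  P <- matrix(0, n, n)
  P[net$edges] <- 1 / outdeg[net$edges[, 1L]]
  # sources that can reach the destination (reverse reachability)
  g <- as_igraph(net)
  reach <- net$nodes[as.integer(
    igraph::subcomponent(g, v = net$nodes[d], mode = "in"))]
  can <- net$nodes %in% reach
  trans <- setdiff(which(can), d)
  V <- matrix(NA_real_, n, n, dimnames = list(net$nodes, net$nodes))
  if (length(trans)) {
    Q <- P[trans, trans, drop = FALSE]
    Fm <- solve(diag(length(trans)) - Q)
    V[trans, ] <- 0
    V[trans, trans] <- Fm
    V[trans, d] <- 0
  }
  V[d, ] <- 0  # a unit created at its destination does not occur (source != dest)
  V
}

#' Effective per-node arrival rates from the traffic equations
#'
#' Composes the absorbing-walk visit counts over all ordered
#' (source, destination) pairs into the total arrival rate each node sees:
#' `lambda_i = lambda / (N (N - 1)) * sum over pairs (s != d) of
#' E[visits to i | walk from s absorbed at d]`. The external injection at
#' the source is included because the walk's starting visit counts. Rates
#' are linear in `lambda`. Pairs whose destination is unreachable from the
#' source are excluded from the sum; their count is attached as attribute
#' `n_excluded_pairs`.
#'
#' @param net a [directed_network()]
#' @param lambda_ext network-global external arrival rate
#' @return named numeric vector of per-node arrival rates
#' @export
node_arrival_rates <- function(net, lambda_ext) {
  n <- n_nodes(net)
  total <- numeric(n)
  excluded <- 0L
  for (d in seq_len(n)) {
    V <- absorbing_visit_counts(net, d)
    src <- setdiff(seq_len(n), d)
    bad <- src[is.na(V[src, 1L])]
    excluded <- excluded + length(bad)
    good <- setdiff(src, bad)
    if (length(good)) {
      total <- total + colSums(V[good, , drop = FALSE])
    }
  }
  rates <- lambda_ext / (n * (n - 1)) * total
  names(rates) <- net$nodes
  attr(rates, "n_excluded_pairs") <- excluded
  rates
}

#' Finite-buffer single-server queue formulas (M/M/1/c)
#'
#' Stationary metrics of the M/M/1 queue with total capacity `capacity`
#' (server plus buffer): with `rho = arrival_rate / mu`, the occupancy law
#' is `p_n = rho^n (1 - rho) / (1 - rho^(capacity + 1))` (uniform when
#' `rho = 1`). Utilization is `1 - p_0`, the loss fraction is `p_capacity`
#' (by PASTA this is also the blocking probability of the push-out buffer,
#' whose occupancy chain is identical to block-on-arrival), and mean
#' contents is `sum n p_n`.
#'
#' @param arrival_rate effective arrival rate (vectorized)
#' @param mu service rate (> 0)
#' @param capacity total capacity, server slot included (>= 1); for a
#'   buffer of size K use `capacity = K + 1`
#' @return data frame with columns `utilization`, `blocking`,
#'   `mean_contents`
#' @export
mm1k_metrics <- function(arrival_rate, mu, capacity) {
  if (capacity < 1L) stop("capacity must be >= 1")
  if (mu <= 0) stop("mu must be positive")
  one <- function(lam) {
    if (lam == 0) return(c(0, 0, 0))
    rho <- lam / mu
    nvec <- 0:capacity
    p <- if (abs(rho - 1) < 1e-12) rep(1 / (capacity + 1), capacity + 1L) else
      rho^nvec * (1 - rho) / (1 - rho^(capacity + 1))
    c(1 - p[1L], p[capacity + 1L], sum(nvec * p))
  }
  res <- t(vapply(arrival_rate, one, numeric(3)))
  data.frame(utilization = res[, 1L], blocking = res[, 2L],
             mean_contents = res[, 3L])
}

#' Analytic steady-state prediction for a whole network
#'
#' The package's analytic verification model: the absorbing-random-walk
#' traffic equations give each node's effective arrival rate, which feeds
#' the finite-buffer single-server formulas with capacity `K + 1`. This is
#' an open-network decomposition approximation — it treats nodes as
#' independent and ignores blocking-induced flow thinning (LIFO order does
#' not affect the occupancy law) — so it is accurate at low load and
#' degrades as blocking grows; its role is as an independent check on the
#' simulator.
#'
#' @param net a [directed_network()]
#' @param config a [sim_config()]
#' @return list of class `analytic_prediction`: `node` data frame
#'   (`node`, `arrival_rate`, `utilization`, `blocking`, `mean_contents`)
#'   and `network` one-row data frame of means.
#' @export
predict_stats <- function(net, config) {
  lambda <- if (config$arrival_mode == "global") config$lambda else
    config$lambda * n_nodes(net)
  rates <- node_arrival_rates(net, lambda)
  mm <- mm1k_metrics(as.numeric(rates), config$mu, config$buffer_size + 1L)
  node <- data.frame(node = net$nodes, arrival_rate = as.numeric(rates), mm,
                     stringsAsFactors = FALSE)
  network <- data.frame(
    mean_utilization = mean(node$utilization),
    mean_blocking = mean(node$blocking),
    mean_contents = mean(node$mean_contents)
  )
  structure(list(node = node, network = network,
                 n_excluded_pairs = attr(rates, "n_excluded_pairs")),
            class = "analytic_prediction")
}

#' @export
print.analytic_prediction <- function(x, ...) {
  cat("analytic_prediction:", nrow(x$node), "nodes; mean utilization",
      signif(x$network$mean_utilization, 4), "\n")
  invisible(x)
}
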