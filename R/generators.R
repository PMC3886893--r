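#' Degree-preserving randomization by Markov edge switching
#'
#' Randomizes a directed network while preserving every node's in-degree and
#' out-degree exactly. Each accepted swap exchanges the targets of two
#' randomly chosen edges, (A->B, C->D) => (A->D, C->B); candidate swaps that
#' would create a self-loop or a duplicate edge are rejected and do not count
#' towards `n_swaps`. This is the null model behind the normalized rich-club
#' coefficient and the "randomized" surrogate family.
#'
#' @param net a [directed_network()] with at least 2 edges
#' @param n_swaps number of *accepted* swaps to perform; default 10 per edge
#' @param seed optional integer seed (`set.seed`) for reproducibility
#' @param max_attempts bound on total attempts; if reached before `n_swaps`
#'   accepted swaps the current state is returned with attribute
#'   `rewire_info$exhausted = TRUE` and a warning
#' @return a new `directed_network` with identical degree vectors; attribute
#'   `rewire_info` records accepted/attempted swap counts.
#' @export
maslov_rewire <- function(net, n_swaps = 10L * n_edges(net), seed = NULL,
                          max_attempts = 100 * n_swaps) {
  if (n_edges(net) < 2L) stop("need at least 2 edges to rewire")
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_rewire(net$edges - 1L, n_nodes(net),
                    n_swaps = as.double(n_swaps),
                    max_attempts = as.double(max(max_attempts, 1)),
                    lattice = FALSE,
                    order_index = net$order_index - 1L,
                    stop_rejects = -1, displace_target = -1)
  if (res$exhausted) {
    warning("rewiring stopped after ", format(res$attempts, scientific = FALSE),
            " attempts with ", res$accepted, " of ", n_swaps,
            " requested swaps accepted")
  }
  out <- directed_network(res$edges + 1L, nodes = net$nodes,
                          order_index = net$order_index)
  attr(out, "rewire_info") <- res[c("accepted", "attempts", "exhausted",
                                    "displaced")]
  out
}

#' Latticization by cost-decreasing edge switching
#'
#' Same swap mechanics as [maslov_rewire()], but a swap is accepted only if
#' it strictly decreases the lattice cost
#' `sum over edges of |order_index(source) - order_index(target)|`,
#' pulling edges towards the diagonal of the ordered adjacency matrix and so
#' towards a ring-lattice-like topology while preserving degrees exactly.
#' By default swapping runs until `10 * n_edges` consecutive candidate swaps
#' have been rejected, which is treated as convergence to a local optimum.
#'
#' @inheritParams maslov_rewire
#' @param n_swaps maximum accepted swaps (`Inf` = run to convergence)
#' @param stop_rejects consecutive-rejection convergence threshold
#' @return a degree-matched latticized `directed_network`; attribute
#'   `rewire_info` as in [maslov_rewire()].
#' @export
latticize <- function(net, n_swaps = Inf, seed = NULL,
                      stop_rejects = 10L * n_edges(net),
                      max_attempts = 1e7) {
  if (n_edges(net) < 2L) stop("need at least 2 edges to latticize")
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_rewire(net$edges - 1L, n_nodes(net),
                    n_swaps = if (is.finite(n_swaps)) as.double(n_swaps) else -1,
                    max_attempts = as.double(max_attempts),
                    lattice = TRUE,
                    order_index = net$order_index - 1L,
                    stop_rejects = as.double(stop_rejects),
                    displace_target = -1)
  out <- directed_network(res$edges + 1L, nodes = net$nodes,
                          order_index = net$order_index)
  attr(out, "rewire_info") <- res[c("accepted", "attempts", "exhausted",
                                    "displaced")]
  out
}

#' Lattice cost of a network
#'
#' The quantity minimized by [latticize()]: the sum over edges of the
#' absolute order-index distance between the endpoints.
#'
#' @param net a `directed_network`
#' @return non-negative number
#' @export
lattice_cost <- function(net) {
  o <- net$order_index
  sum(abs(o[net$edges[, 1L]] - o[net$edges[, 2L]]))
}

#' Directed ring lattice
#'
#' Each node sends one directed edge to each of its `k_neighbors` nearest
#' successors and `k_neighbors` nearest predecessors on the ring, so every
#' node has in-degree and out-degree `2 * k_neighbors`.
#'
#' @param n number of nodes (must exceed `2 * k_neighbors`)
#' @param k_neighbors neighbourhood radius
#' @return a `directed_network` with `n * 2 * k_neighbors` edges
#' @export
ring_lattice <- function(n, k_neighbors) {
  if (n <= 2L * k_neighbors) stop("need n > 2 * k_neighbors")
  i <- rep(seq_len(n), each = 2L * k_neighbors)
  off <- rep(c(seq_len(k_neighbors), -seq_len(k_neighbors)), times = n)
  j <- ((i - 1L + off) %% n) + 1L
  directed_network(cbind(i, j), nodes = paste0("n", seq_len(n)))
}

#' Small-world network from a perturbed ring lattice
#'
#' Builds a directed ring lattice and then displaces a fraction of its edges.
#' The default method applies degree-preserving double-edge swaps
#' ([maslov_rewire()] mechanics) until `ceiling(fraction * n_edges)` edges
#' differ from their lattice positions, so the small-world network stays
#' exactly degree-matched to its lattice control. `method = "retarget"`
#' offers the classic rewire-to-a-random-target variant, which preserves
#' out-degrees but not in-degrees.
#'
#' @inheritParams ring_lattice
#' @param fraction proportion of edges to displace (default 0.10; 0 returns
#'   the pristine lattice)
#' @param seed optional integer seed
#' @param method `"swap"` (degree-preserving, default) or `"retarget"`
#' @return a `directed_network`
#' @export
small_world <- function(n, k_neighbors, fraction = 0.10, seed = NULL,
                        method = c("swap", "retarget")) {
  method <- match.arg(method)
  lat <- ring_lattice(n, k_neighbors)
  if (fraction <= 0) return(lat)
  if (!is.null(seed)) set.seed(seed)
  m <- n_edges(lat)
  target <- ceiling(fraction * m)
  if (method == "swap") {
    res <- cpp_rewire(lat$edges - 1L, n, n_swaps = -1,
                      max_attempts = 1000 * m, lattice = FALSE,
                      order_index = lat$order_index - 1L,
                      stop_rejects = -1,
                      displace_target = as.double(target))
    if (res$exhausted) warning("edge displacement target not reached")
    out <- directed_network(res$edges + 1L, nodes = lat$nodes)
    attr(out, "rewire_info") <- res[c("accepted", "attempts", "exhausted",
                                      "displaced")]
    out
  } else {
    edges <- lat$edges
    pick <- sample.int(m, target)
    key <- paste(edges[, 1L], edges[, 2L])
    for (e in pick) {
      repeat {
        j <- sample.int(n, 1L)
        k <- paste(edges[e, 1L], j)
        if (j != edges[e, 1L] && !(k %in% key)) {
          key[e] <- k
          edges[e, 2L] <- j
          break
        }
      }
    }
    directed_network(edges, nodes = lat$nodes)
  }
}

#' Erdős–Rényi-style random directed network
#'
#' Each ordered pair of distinct nodes is connected independently with
#' probability `p`. By default the draw is repeated (continuing the RNG
#' stream) until every node has in-degree and out-degree at least 1, so the
#' result can host the communication model.
#'
#' @param n number of nodes
#' @param p connection probability per ordered pair
#' @param seed optional integer seed
#' @param require_simulatable regenerate until [check_simulatable()] passes
#' @param max_tries regeneration bound
#' @return a `directed_network`
#' @export
random_directed <- function(n, p, seed = NULL, require_simulatable = TRUE,
                            max_tries = 100L) {
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_tries)) {
    a <- matrix(stats::runif(n * n) < p, n, n)
    diag(a) <- FALSE
    idx <- which(a, arr.ind = TRUE)
    net <- directed_network(matrix(as.integer(idx), ncol = 2L),
                            nodes = paste0("n", seq_len(n)))
    if (!require_simulatable || check_simulatable(net)$ok) return(net)
  }
  stop("could not generate a simulatable network in ", max_tries, " tries")
}

#' Synthetic network with a planted rich club
#'
#' A random directed network in which a designated subset of nodes (the rich
#' club) is wired with a density gradient: non-club ordered pairs connect
#' with probability `p_local`, club-to-non-club pairs (either direction) with
#' `p_feeder`, and club-to-club pairs with `p_rich`. With
#' `p_local < p_feeder < p_rich` this plants both the high degree of club
#' nodes and their mutual over-connection that the rich-club coefficient
#' detects. The draw is repeated (new RNG stream values) until the degree
#' floor of [check_simulatable()] is satisfied.
#'
#' @param n total nodes (default 100)
#' @param n_rc rich-club size (default 20); planted members are the first
#'   `n_rc` nodes
#' @param p_local,p_feeder,p_rich block connection probabilities in (0, 1],
#'   non-decreasing
#' @param seed optional integer seed
#' @param max_tries regeneration bound
#' @return a `directed_network` with attribute `rc_members` (character
#'   vector of planted club node labels).
#' @export
rich_club_synthetic <- function(n = 100L, n_rc = 20L, p_local = 0.05,
                                p_feeder = 0.20, p_rich = 0.80, seed = NULL,
                                max_tries = 100L) {
  probs <- c(p_local, p_feeder, p_rich)
  if (any(probs <= 0 | probs > 1)) stop("probabilities must lie in (0, 1]")
  if (p_local > p_feeder || p_feeder > p_rich) {
    stop("need p_local <= p_feeder <= p_rich")
  }
  if (n_rc >= n) stop("need n_rc < n")
  if (!is.null(seed)) set.seed(seed)
  club <- seq_len(n_rc)
  in_club <- seq_len(n) %in% club
  pm <- matrix(p_local, n, n)
  pm[in_club, ] <- p_feeder
  pm[, in_club] <- p_feeder
  pm[in_club, in_club] <- p_rich
  for (try in seq_len(max_tries)) {
    a <- matrix(stats::runif(n * n), n, n) < pm
    diag(a) <- FALSE
    idx <- which(a, arr.ind = TRUE)
    net <- directed_network(matrix(as.integer(idx), ncol = 2L),
                            nodes = paste0("n", seq_len(n)))
    if (check_simulatable(net)$ok) {
      attr(net, "rc_members") <- net$nodes[club]
      return(net)
    }
  }
  stop("could not generate a simulatable rich-club network in ",
       max_tries, " tries")
}
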