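#' Exact stationary node contents by brute-force CTMC solve
#'
#' Builds the full continuous-time Markov chain of the communication model
#' on a (tiny) network and solves for its stationary distribution. The state
#' records, for every node, the ordered sequence of destinations of the
#' units it holds (first = in service, then the queue from oldest to
#' newest); this is the minimal state under LIFO service, push-out ejection
#' of the oldest queued unit and destination-dependent routing removal.
#' Transitions: external arrivals at rate `lambda / (N (N - 1))` per ordered
#' (source, destination) pair, and service completions at rate `mu / outdeg`
#' per out-neighbour, with absorption when the hop lands on the unit's
#' destination. The state space grows as
#' `prod_i sum_{c = 0..K+1} (N - 1)^c`, so this is strictly a small-network
#' verification oracle for the event-driven simulator, not a scalable
#' solver.
#'
#' @param net a [directed_network()] (a few nodes at most)
#' @param lambda network-global external arrival rate
#' @param mu service rate
#' @param buffer_size queue capacity K
#' @param max_states guard on the state-space size (default 50000)
#' @return data frame with one row per node: `node`, `mean_contents`
#'   (stationary expectation of X_i), `utilization` (stationary probability
#'   the node is busy)
#' @export
stationary_node_contents <- function(net, lambda, mu, buffer_size,
                                     max_states = 5e4) {
  n <- n_nodes(net)
  K <- as.integer(buffer_size)
  cap <- K + 1L
  nbr <- lapply(seq_len(n), function(i) net$edges[net$edges[, 1L] == i, 2L])
  if (any(lengths(nbr) == 0L)) stop("every node needs an out-neighbour")

  # enumerate per-node local states: sequences over destinations != i
  local_states <- lapply(seq_len(n), function(i) {
    dests <- setdiff(seq_len(n), i)
    out <- list(integer(0))
    for (len in seq_len(cap)) {
      grids <- rep(list(dests), len)
      combos <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
      out <- c(out, lapply(seq_len(nrow(combos)),
                           function(r) as.integer(combos[r, ])))
    }
    out
  })
  sizes <- lengths(local_states)
  n_states <- prod(sizes)
  if (n_states > max_states) {
    stop("state space too large (", n_states, " states)")
  }

  # global states = tuples of local-state indices; mixed-radix encoding
  radix <- cumprod(c(1, sizes[-n]))
  encode <- function(idx) sum((idx - 1L) * radix) + 1L
  decode <- function(s) {
    s <- s - 1L
    idx <- integer(n)
    for (i in seq_len(n)) {
      idx[i] <- s %% sizes[i] + 1L
      s <- s %/% sizes[i]
    }
    idx
  }
  local_index <- lapply(seq_len(n), function(i) {
    keys <- vapply(local_states[[i]], function(s)
      paste0("s", paste(s, collapse = ",")), character(1))
    stats::setNames(seq_along(keys), keys)
  })
  find_local <- function(i, seqv) {
    local_index[[i]][[paste0("s", paste(seqv, collapse = ","))]]
  }

  # apply an arrival of a unit with destination dd at node j
  arrive <- function(state_idx, j, dd) {
    s <- local_states[[j]][[state_idx[j]]]
    s <- c(s, dd)
    if (length(s) - 1L > K) s <- s[-2L]  # eject oldest queued
    state_idx[j] <- find_local(j, s)
    state_idx
  }

  max_trans <- n_states * (n * (n - 1L) + sum(lengths(nbr)))
  trip_i <- integer(max_trans)
  trip_j <- integer(max_trans)
  trip_x <- numeric(max_trans)
  n_tr <- 0L
  add <- function(from, to, rate) {
    n_tr <<- n_tr + 1L
    trip_i[n_tr] <<- from
    trip_j[n_tr] <<- to
    trip_x[n_tr] <<- rate
  }

  pair_rate <- lambda / (n * (n - 1))
  for (s in seq_len(n_states)) {
    idx <- decode(s)
    # external arrivals
    if (lambda > 0) {
      for (src in seq_len(n)) for (dd in seq_len(n)) {
        if (dd == src) next
        add(s, encode(arrive(idx, src, dd)), pair_rate)
      }
    }
    # service completions
    for (i in seq_len(n)) {
      loc <- local_states[[i]][[idx[i]]]
      if (!length(loc)) next
      dd <- loc[1L]
      rest <- loc[-1L]
      if (length(rest)) rest <- c(rest[length(rest)], rest[-length(rest)])
      idx2 <- idx
      idx2[i] <- find_local(i, rest)
      hop_rate <- mu / length(nbr[[i]])
      for (jn in nbr[[i]]) {
        to <- if (jn == dd) idx2 else arrive(idx2, jn, dd)
        add(s, encode(to), hop_rate)
      }
    }
  }

  trip_i <- trip_i[seq_len(n_tr)]
  trip_j <- trip_j[seq_len(n_tr)]
  trip_x <- trip_x[seq_len(n_tr)]
  Q <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(n_states, n_states))
  diag_out <- Matrix::rowSums(Q)
  Q <- Q - Matrix::Diagonal(n_states, diag_out)
  # stationary distribution: pi Q = 0, sum pi = 1
  A <- Matrix::t(Q)
  A[n_states, ] <- 1
  b <- c(rep(0, n_states - 1L), 1)
  pi_vec <- as.numeric(Matrix::solve(A, b))
  pi_vec[pi_vec < 0 & pi_vec > -1e-12] <- 0
  pi_vec <- pi_vec / sum(pi_vec)

  contents <- matrix(0, n_states, n)
  for (s in seq_len(n_states)) {
    idx <- decode(s)
    contents[s, ] <- vapply(seq_len(n), function(i)
      length(local_states[[i]][[idx[i]]]), integer(1))
  }
  data.frame(
    node = net$nodes,
    mean_contents = as.numeric(crossprod(pi_vec, contents)),
    utilization = as.numeric(crossprod(pi_vec, contents >= 1)),
    stringsAsFactors = FALSE
  )
}
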