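# Shared fixtures and independent oracles used across the suite.
# Oracles deliberately avoid the package's own computation paths.

two_node_net <- function() {
  directed_network(rbind(c("A", "B"), c("B", "A")))
}

# fully connected directed triangle (all 6 ordered pairs)
triangle_net <- function() {
  directed_network(cbind(rep(1:3, each = 2), c(2, 3, 1, 3, 1, 2)),
                   nodes = c("A", "B", "C"))
}

# Birth-death CTMC stationary distribution for a single-server queue with
# total capacity `cap`: dense generator solve, independent of the
# closed-form geometric expression in mm1k_metrics().
bd_stationary <- function(lambda, mu, cap) {
  n <- cap + 1L
  Q <- matrix(0, n, n)
  for (s in seq_len(n) - 1L) {
    if (s < cap) Q[s + 1L, s + 2L] <- lambda
    if (s > 0) Q[s + 1L, s] <- mu
  }
  diag(Q) <- -rowSums(Q)
  A <- t(Q)
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  solve(A, b)
}

# Brute-force rich-club density: explicit node stripping and double loop
# over surviving ordered pairs on the adjacency matrix.
brute_phi <- function(net, k) {
  a <- as_adjacency(net)
  deg <- rowSums(a) + colSums(a)
  keep <- which(deg > k)
  m <- length(keep)
  if (m < 2L) return(NA_real_)
  cnt <- 0L
  for (i in keep) for (j in keep) if (i != j && a[i, j] == 1L) cnt <- cnt + 1L
  cnt / (m * (m - 1))
}

# Monte-Carlo expected visit counts of the absorbing uniform random walk
# (counts the start node; never counts the destination).
mc_visits <- function(net, source, destination, n_walks, max_len = 10000L) {
  nbr <- lapply(seq_len(n_nodes(net)),
                function(i) net$edges[net$edges[, 1L] == i, 2L])
  s <- if (is.character(source)) match(source, net$nodes) else source
  d <- if (is.character(destination)) match(destination, net$nodes) else
    destination
  acc <- numeric(n_nodes(net))
  for (w in seq_len(n_walks)) {
    cur <- s
    for (step in seq_len(max_len)) {
      acc[cur] <- acc[cur] + 1
      nxt <- nbr[[cur]]
      cur <- nxt[sample.int(length(nxt), 1L)]
      if (cur == d) break
    }
  }
  acc / n_walks
}

# piecewise-constant occupancy of one node reconstructed from segments,
# evaluated at time t (for buffer-bound and LIFO checks)
node_occupancy_at <- function(trace, node, t) {
  seg <- trace$segments
  sel <- seg$node == node & seg$t_arrive <= t &
    (is.na(seg$t_depart) | seg$t_depart > t)
  sum(sel)
}
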