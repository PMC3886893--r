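test_that("maslov rewiring preserves degree vectors and edge count", {
  for (s in 1:10) {
    net <- random_directed(30, 0.12, seed = s, require_simulatable = FALSE)
    rw <- maslov_rewire(net, seed = 100 + s)
    expect_equal(degrees(rw)$in_degree, degrees(net)$in_degree)
    expect_equal(degrees(rw)$out_degree, degrees(net)$out_degree)
    expect_equal(n_edges(rw), n_edges(net))
  }
})

test_that("rewiring with zero swaps is the identity", {
  net <- random_directed(20, 0.2, seed = 1)
  expect_identical(maslov_rewire(net, n_swaps = 0, seed = 2)$edges, net$edges)
  expect_identical(latticize(net, n_swaps = 0, seed = 2)$edges, net$edges)
})

test_that("the 2-cycle has no legal swap and is returned unchanged", {
  net <- two_node_net()
  expect_warning(rw <- maslov_rewire(net, n_swaps = 5, max_attempts = 200),
                 "attempts")
  expect_setequal(paste(rw$edges[, 1], rw$edges[, 2]),
                  paste(net$edges[, 1], net$edges[, 2]))
})

test_that("latticization never increases the lattice cost and preserves degrees", {
  for (s in 1:5) {
    net <- random_directed(30, 0.1, seed = 20 + s, require_simulatable = FALSE)
    c0 <- lattice_cost(net)
    lat <- latticize(net, seed = 50 + s)
    expect_lte(lattice_cost(lat), c0)
    expect_equal(degrees(lat)$in_degree, degrees(net)$in_degree)
    expect_equal(degrees(lat)$out_degree, degrees(net)$out_degree)
  }
})

test_that("a cost-minimal network admits no accepted lattice swaps", {
  # bidirectional chain: every edge already has the minimum possible
  # order-distance (1), so no swap can strictly decrease the cost
  net <- directed_network(cbind(c(1, 2, 2, 3, 3, 4), c(2, 1, 3, 2, 4, 3)),
                          nodes = paste0("n", 1:4))
  lat <- latticize(net, seed = 3)
  expect_identical(lat$edges, net$edges)
  expect_equal(attr(lat, "rewire_info")$accepted, 0)
})

test_that("ring lattice has the forced regular structure", {
  rl <- ring_lattice(5, 1)
  expect_equal(n_edges(rl), 10L)
  d <- degrees(rl)
  expect_true(all(d$in_degree == 2L) && all(d$out_degree == 2L))
  rl2 <- ring_lattice(100, 2)
  expect_equal(n_edges(rl2), 400L)
  chk <- check_simulatable(rl2)
  expect_true(chk$ok)
  expect_true(chk$strongly_connected)
  expect_error(ring_lattice(4, 2), "k_neighbors")
})

test_that("small-world generator displaces edges while preserving degrees", {
  lat <- ring_lattice(100, 2)
  expect_identical(small_world(100, 2, fraction = 0)$edges, lat$edges)
  sw <- small_world(100, 2, fraction = 0.10, seed = 5)
  expect_equal(degrees(sw)$in_degree, degrees(lat)$in_degree)
  expect_equal(degrees(sw)$out_degree, degrees(lat)$out_degree)
  displaced <- length(setdiff(paste(sw$edges[, 1], sw$edges[, 2]),
                              paste(lat$edges[, 1], lat$edges[, 2])))
  expect_gte(displaced, 40L)
})

test_that("heavy rewiring keeps degrees but destroys lattice positions", {
  lat <- ring_lattice(60, 2)
  rnd <- maslov_rewire(lat, n_swaps = 100L * n_edges(lat), seed = 8)
  expect_equal(degrees(rnd)$in_degree, degrees(lat)$in_degree)
  expect_equal(degrees(rnd)$out_degree, degrees(lat)$out_degree)
  displaced <- length(setdiff(paste(rnd$edges[, 1], rnd$edges[, 2]),
                              paste(lat$edges[, 1], lat$edges[, 2])))
  expect_gt(displaced, 0.8 * n_edges(lat))
})

test_that("planted rich-club densities respect the block gradient", {
  net <- rich_club_synthetic(n = 100, n_rc = 20, seed = 42)
  club <- net$nodes %in% attr(net, "rc_members")
  expect_length(attr(net, "rc_members"), 20L)
  a <- as_adjacency(net)
  d_rich <- sum(a[club, club]) / (20 * 19)
  d_local <- sum(a[!club, !club]) / (80 * 79)
  d_feeder <- (sum(a[club, !club]) + sum(a[!club, club])) / (2 * 20 * 80)
  # binomial 3-SE bands around the target densities
  expect_lt(abs(d_rich - 0.80), 3 * sqrt(0.8 * 0.2 / (20 * 19)))
  expect_lt(abs(d_feeder - 0.20), 3 * sqrt(0.2 * 0.8 / (2 * 20 * 80)))
  expect_lt(abs(d_local - 0.05), 3 * sqrt(0.05 * 0.95 / (80 * 79)))
  expect_gt(d_rich, d_feeder)
  expect_gt(d_feeder, d_local)
})

test_that("degenerate equal densities are allowed and give no gradient", {
  net <- rich_club_synthetic(n = 60, n_rc = 10, p_local = 0.2,
                             p_feeder = 0.2, p_rich = 0.2, seed = 9)
  expect_s3_class(net, "directed_network")
  expect_error(rich_club_synthetic(p_local = 0.5, p_feeder = 0.2,
                                   p_rich = 0.8), "p_local")
  expect_error(rich_club_synthetic(p_rich = 1.5), "probabilities")
})

test_that("generators are deterministic given a seed", {
  expect_identical(rich_club_synthetic(seed = 7)$edges,
                   rich_club_synthetic(seed = 7)$edges)
  expect_identical(small_world(50, 2, seed = 7)$edges,
                   small_world(50, 2, seed = 7)$edges)
  net <- random_directed(40, 0.1, seed = 7)
  expect_identical(maslov_rewire(net, seed = 8)$edges,
                   maslov_rewire(net, seed = 8)$edges)
  expect_identical(latticize(net, seed = 8)$edges,
                   latticize(net, seed = 8)$edges)
})
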