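# hand-built trace: full control over segments for exact-integral checks
make_trace <- function(units, segments, net, t_end, t_transient = 0) {
  structure(
    list(units = units, segments = segments, net = net,
         config = sim_config(1, 1, 5, t_end, t_transient),
         window = c(t_transient, t_end)),
    class = "sim_trace")
}

hand_net <- function() directed_network(rbind(c("A", "B"), c("B", "A")))

test_that("windowed node statistics match hand integrals", {
  # one unit at node A: waits [1, 2], serves [2, 5], departs; another unit
  # ejected at node B after queueing [3, 4]
  units <- data.frame(
    uid = 1:2, source = c("A", "B"), destination = c("B", "A"),
    t_created = c(1, 3),
    status = factor(c("delivered", "dropped"),
                    levels = c("in_network", "delivered", "dropped")),
    t_final = c(5, 4))
  segments <- data.frame(
    uid = 1:2, node = c(1L, 2L), t_arrive = c(1, 3),
    t_service_start = c(2, NA), t_depart = c(5, 4))
  tr <- make_trace(units, segments, hand_net(), t_end = 10)
  ns <- node_stats(tr)
  expect_equal(ns$utilization, c(3 / 10, 0))
  expect_equal(ns$mean_contents, c(4 / 10, 1 / 10))
  expect_equal(ns$blocking, c(0, 1))
  expect_equal(ns$arrivals, c(1L, 1L))
  # clipping: window [3, 10] sees only 2 units of A's service time
  ns2 <- node_stats(tr, window = c(3, 10))
  expect_equal(ns2$utilization[1], 2 / 7)
  expect_equal(ns2$mean_contents[1], 2 / 7)
})

test_that("transit time is the sum of waiting and service times", {
  # W = 0.5 then S = 1.2 at node A, delivered on the hop at t = 1.7
  units <- data.frame(
    uid = 1L, source = "A", destination = "B", t_created = 0,
    status = factor("delivered",
                    levels = c("in_network", "delivered", "dropped")),
    t_final = 1.7)
  segments <- data.frame(uid = 1L, node = 1L, t_arrive = 0,
                         t_service_start = 0.5, t_depart = 1.7)
  tr <- make_trace(units, segments, hand_net(), t_end = 10)
  st <- network_stats(tr)
  expect_equal(st$mean_transit_time, 1.7)
  expect_equal(st$throughput, 1L)
})

test_that("empty windows flag statistics instead of fabricating zeros", {
  units <- data.frame(
    uid = integer(0), source = character(0), destination = character(0),
    t_created = numeric(0),
    status = factor(character(0),
                    levels = c("in_network", "delivered", "dropped")),
    t_final = numeric(0))
  segments <- data.frame(uid = integer(0), node = integer(0),
                         t_arrive = numeric(0), t_service_start = numeric(0),
                         t_depart = numeric(0))
  tr <- make_trace(units, segments, hand_net(), t_end = 10)
  ns <- node_stats(tr)
  expect_true(all(is.na(ns$blocking)))
  expect_true(all(ns$utilization == 0))
  st <- network_stats(tr)
  expect_equal(st$throughput, 0L)
  expect_true(is.na(st$mean_transit_time))
})

test_that("transient removal validates its cutoff", {
  tr <- run_simulation(two_node_net(), sim_config(0.5, 1, 2, 100, 0, seed = 2))
  expect_error(remove_transient(tr, 100), "t_end")
  full <- remove_transient(tr, 0)
  expect_equal(full$window, c(0, 100))
})

test_that("conservation identities hold on simulated traces", {
  net <- random_directed(10, 0.3, seed = 8)
  tr <- run_simulation(net, sim_config(0.8, 1, 3, 1000, 100, seed = 9))
  hops <- trace_hops(tr)
  w <- tr$window
  et <- edge_throughput(tr)
  expect_equal(sum(et$throughput),
               sum(hops$t >= w[1] & hops$t < w[2]))
  ps <- path_stats(tr)
  st <- network_stats(tr)
  expect_equal(sum(ps$deliveries), st$throughput)
  expect_equal(sum(ps$by_source$mean_deliveries) * (n_nodes(net) - 1),
               sum(ps$deliveries))
})

test_that("edge throughput respects membership classes", {
  net <- random_directed(10, 0.35, seed = 12)
  tr <- run_simulation(net, sim_config(0.8, 1, 3, 500, 0, seed = 13))
  med <- stats::median(degrees(net)$total_degree)
  memb <- classify_nodes(net, med, med)
  et <- edge_throughput(tr, membership = memb)
  expect_true(!is.null(attr(et, "class_means")))
  expect_equal(sum(et$throughput), nrow(trace_hops(tr)) -
                 sum(trace_hops(tr)$t >= tr$window[2]) -
                 sum(trace_hops(tr)$t < tr$window[1]))
})

test_that("load series reflects unit lifetimes exactly", {
  units <- data.frame(
    uid = 1L, source = "A", destination = "B", t_created = 2,
    status = factor("delivered",
                    levels = c("in_network", "delivered", "dropped")),
    t_final = 7)
  segments <- data.frame(uid = 1L, node = 1L, t_arrive = 2,
                         t_service_start = 2, t_depart = 7)
  tr <- make_trace(units, segments, hand_net(), t_end = 10)
  ls <- load_series(tr)
  expect_equal(ls$N, c(0, 1, 0))
  expect_equal(ls$time, c(0, 2, 7))
})

test_that("mean load from the series equals summed node contents", {
  net <- random_directed(8, 0.35, seed = 21)
  tr <- run_simulation(net, sim_config(0.6, 1, 3, 800, 0, seed = 22))
  ls <- load_series(tr)
  # time-average of the piecewise-constant N(t) over [0, t_end]
  tt <- c(ls$time, tr$config$t_end)
  avg_N <- sum(ls$N * diff(tt)) / tr$config$t_end
  ns <- node_stats(tr, window = c(0, tr$config$t_end))
  expect_equal(avg_N, sum(ns$mean_contents), tolerance = 1e-10)
})

test_that("interpolation is linear and the identity on uniform grids", {
  s <- data.frame(time = c(0, 10), value = c(0, 10))
  out <- interpolate_uniform(s, 5)
  expect_equal(out$value, c(0, 5, 10))
  u <- data.frame(time = seq(0, 6, by = 2), value = c(1, 4, 2, 8))
  expect_equal(interpolate_uniform(u, 2)$value, u$value)
  expect_error(interpolate_uniform(u[0, ], 1), "empty")
  # interpolation error is bounded by the largest jump of the step series
  tr <- run_simulation(two_node_net(), sim_config(1, 1, 3, 300, 0, seed = 5))
  ls <- load_series(tr)
  ip <- interpolate_uniform(ls, 0.5)
  step_val <- vapply(ip$time, function(t) ls$N[max(which(ls$time <= t))],
                     numeric(1))
  expect_lte(max(abs(ip$value - step_val)), max(abs(diff(ls$N))))
})

test_that("ensemble-average warmup detection finds a constructed ramp", {
  tt <- seq(0, 400, by = 1)
  mk <- function(seed) {
    set.seed(seed)
    ramp <- pmin(tt / 100, 1) * 10
    data.frame(time = tt, value = ramp + rnorm(length(tt), 0, 0.1))
  }
  t0 <- detect_transient(lapply(1:20, mk), tolerance = 0.05)
  expect_gte(t0, 80)
  expect_lte(t0, 130)
  flat <- lapply(21:30, function(s) {
    set.seed(s)
    data.frame(time = tt, value = 5 + rnorm(length(tt), 0, 0.05))
  })
  expect_lte(detect_transient(flat, tolerance = 0.05), 20)
  ramp_only <- lapply(1:3, function(s) data.frame(time = tt, value = tt))
  expect_warning(t_bad <- detect_transient(ramp_only, tolerance = 1e-4),
                 "stabilize")
  expect_equal(t_bad, 400)
})
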