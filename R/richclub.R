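#' Rich-club coefficient at a single degree threshold
#'
#' Strips all nodes with degree `<= k` and returns the density of the
#' surviving directed subgraph: surviving edges divided by `m * (m - 1)`
#' possible directed edges among the `m` survivors. Returns `NA` (flagged)
#' when fewer than two nodes survive.
#'
#' @param net a [directed_network()]
#' @param k degree threshold (survivors have degree strictly greater than k)
#' @param degree_type which degree to threshold on: `"total"` (in + out,
#'   default, the usual convention for directed connectomes), `"in"`, or
#'   `"out"`
#' @return density in \[0, 1\], or `NA_real_` if undefined
#' @export
rich_club_coefficient <- function(net, k,
                                  degree_type = c("total", "in", "out")) {
  degree_type <- match.arg(degree_type)
  d <- degrees(net)
  deg <- switch(degree_type, total = d$total_degree, `in` = d$in_degree,
                out = d$out_degree)
  survive <- deg > k
  m <- sum(survive)
  if (m < 2L) return(NA_real_)
  keep <- survive[net$edges[, 1L]] & survive[net$edges[, 2L]]
  sum(keep) / (m * (m - 1))
}

#' Rich-club profile with degree-matched normalization
#'
#' Computes the rich-club coefficient `phi(k)` over the threshold grid from
#' the lowest to the second-highest degree in the network, and normalizes it
#' against `n_null` degree-matched randomized networks ([maslov_rewire()]
#' with `n_swaps_per_edge` accepted swaps per edge):
#' `phi_norm(k) = phi(k) / mean_null(phi(k))`. A `phi_norm` consistently
#' above 1 over a contiguous range of high `k` indicates rich-club
#' organization. The null mean and SD are reported per threshold so profiles
#' computed with a reduced null count remain interpretable.
#'
#' @inheritParams rich_club_coefficient
#' @param n_null number of null networks (default 100; increase towards
#'   10000 for publication-grade profiles)
#' @param n_swaps_per_edge accepted swaps per edge for each null
#' @param seed optional integer seed
#' @return object of class `rich_club_profile`: a data frame with columns
#'   `k`, `phi`, `null_mean`, `null_sd`, `phi_norm`; attribute `n_null`.
#' @export
rich_club_profile <- function(net, n_null = 100L, n_swaps_per_edge = 10L,
                              seed = NULL,
                              degree_type = c("total", "in", "out")) {
  degree_type <- match.arg(degree_type)
  if (n_null < 1L) stop("n_null must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  d <- degrees(net)
  deg <- switch(degree_type, total = d$total_degree, `in` = d$in_degree,
                out = d$out_degree)
  ds <- sort(deg, decreasing = TRUE)
  k_grid <- seq.int(min(deg), ds[2L])
  phi_of <- function(x) {
    dd <- degrees(x)
    dx <- switch(degree_type, total = dd$total_degree, `in` = dd$in_degree,
                 out = dd$out_degree)
    vapply(k_grid, function(k) {
      survive <- dx > k
      m <- sum(survive)
      if (m < 2L) return(NA_real_)
      sum(survive[x$edges[, 1L]] & survive[x$edges[, 2L]]) / (m * (m - 1))
    }, numeric(1))
  }
  phi <- phi_of(net)
  nulls <- matrix(NA_real_, n_null, length(k_grid))
  for (b in seq_len(n_null)) {
    nulls[b, ] <- phi_of(maslov_rewire(net, n_swaps_per_edge * n_edges(net)))
  }
  null_mean <- colMeans(nulls, na.rm = TRUE)
  null_sd <- apply(nulls, 2L, stats::sd, na.rm = TRUE)
  phi_norm <- ifelse(!is.na(null_mean) & null_mean > 0, phi / null_mean,
                     NA_real_)
  out <- data.frame(k = k_grid, phi = phi, null_mean = null_mean,
                    null_sd = null_sd, phi_norm = phi_norm)
  attr(out, "n_null") <- n_null
  attr(out, "degree_type") <- degree_type
  class(out) <- c("rich_club_profile", "data.frame")
  out
}

#' Classify nodes into nested rich-club levels
#'
#' Assigns each node a level in `{none, RC2, RC1}`, where RC1 (the
#' conservative, higher-degree club) is nested inside RC2 (the liberal,
#' lower-degree club): RC1 members have degree `> k_rc1`, RC2 members degree
#' `> k_rc2`, with `k_rc1 >= k_rc2`. Alternatively an explicit membership
#' (e.g. taken from a prior empirical assignment) can be supplied as node
#' label vectors.
#'
#' @inheritParams rich_club_coefficient
#' @param k_rc1,k_rc2 degree thresholds, `k_rc1 >= k_rc2` (ignored when
#'   explicit node lists are given)
#' @param rc1_nodes,rc2_nodes optional explicit node-label vectors; if given,
#'   `rc1_nodes` must be a subset of `rc2_nodes`
#' @return data frame with columns `node` and `rc_level`
#'   (factor none < RC2 < RC1)
#' @export
classify_nodes <- function(net, k_rc1 = NULL, k_rc2 = NULL,
                           rc1_nodes = NULL, rc2_nodes = NULL,
                           degree_type = c("total", "in", "out")) {
  degree_type <- match.arg(degree_type)
  if (!is.null(rc2_nodes)) {
    if (is.null(rc1_nodes)) rc1_nodes <- character(0)
    stopifnot(all(rc1_nodes %in% rc2_nodes),
              all(rc2_nodes %in% net$nodes))
    in1 <- net$nodes %in% rc1_nodes
    in2 <- net$nodes %in% rc2_nodes
  } else {
    if (is.null(k_rc1) || is.null(k_rc2)) {
      stop("supply either (k_rc1, k_rc2) or explicit node lists")
    }
    if (k_rc1 < k_rc2) stop("need k_rc1 >= k_rc2 (RC1 is nested in RC2)")
    d <- degrees(net)
    deg <- switch(degree_type, total = d$total_degree, `in` = d$in_degree,
                  out = d$out_degree)
    in1 <- deg > k_rc1
    in2 <- deg > k_rc2
    if (!any(in2)) warning("RC2 is empty at this threshold")
    if (all(in2)) warning("RC2 contains every node at this threshold")
  }
  lev <- ifelse(in1, "RC1", ifelse(in2, "RC2", "none"))
  data.frame(
    node = net$nodes,
    rc_level = factor(lev, levels = c("none", "RC2", "RC1"), ordered = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Classify edges as rich, feeder or local
#'
#' An edge is `rich` if both endpoints belong to the club at the chosen
#' level, `feeder` if exactly one does, and `local` if neither does. The
#' three classes always partition the edge set.
#'
#' @param net a `directed_network`
#' @param membership data frame from [classify_nodes()] covering every node
#' @param level club level to classify against: `"RC1"` or `"RC2"` (RC1
#'   members count as club members at level RC2 since RC1 is nested)
#' @return data frame with columns `source`, `target`, `class`
#'   (factor rich/feeder/local)
#' @export
classify_edges <- function(net, membership, level = c("RC2", "RC1")) {
  level <- match.arg(level)
  if (!all(net$nodes %in% membership$node)) {
    stop("membership must cover every node in the network")
  }
  lev <- membership$rc_level[match(net$nodes, membership$node)]
  in_club <- if (level == "RC1") lev == "RC1" else lev %in% c("RC1", "RC2")
  a <- in_club[net$edges[, 1L]]
  b <- in_club[net$edges[, 2L]]
  cls <- ifelse(a & b, "rich", ifelse(a | b, "feeder", "local"))
  data.frame(
    source = net$nodes[net$edges[, 1L]],
    target = net$nodes[net$edges[, 2L]],
    class = factor(cls, levels = c("rich", "feeder", "local")),
    stringsAsFactors = FALSE
  )
}
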