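#' Construct a directed, unweighted network
#'
#' The basic data container for all simulation and analysis functions: a set
#' of labelled nodes and a set of ordered (source, target) edges. Self-loops
#' and duplicate edges are rejected — the communication model is defined on
#' inter-regional projections, so a node never transmits to itself and each
#' projection is a single directed edge. Reciprocal edges (A,B) and (B,A) are
#' independent.
#'
#' @param edges two-column matrix or data frame of directed edges
#'   (source, target). Columns may hold node labels (character) or 1-based
#'   integer indices into `nodes`.
#' @param nodes character vector of node labels. Defaults to the labels in
#'   `edges` in order of first appearance (row-wise, source before target).
#'   Supply explicitly to declare isolated nodes or to fix the node order.
#' @param order_index integer position of each node used by [latticize()] as
#'   the lattice coordinate; defaults to the node's position in `nodes`.
#' @return An object of class `directed_network` with elements `nodes`
#'   (character), `edges` (m x 2 integer matrix of node indices) and
#'   `order_index` (integer).
#' @examples
#' net <- directed_network(rbind(c("A", "B"), c("B", "A")))
#' n_edges(net)
#' @export
directed_network <- function(edges, nodes = NULL, order_index = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  if (ncol(edges) != 2L) stop("`edges` must have exactly two columns")
  if (is.numeric(edges)) {
    if (is.null(nodes)) {
      stop("`nodes` must be supplied when `edges` holds integer indices")
    }
    idx <- matrix(as.integer(edges), ncol = 2L)
    if (nrow(idx) && (min(idx) < 1L || max(idx) > length(nodes))) {
      stop("edge index out of range of `nodes`")
    }
  } else {
    lab <- matrix(as.character(edges), ncol = 2L)
    if (is.null(nodes)) {
      nodes <- unique(as.character(t(lab)))
    } else {
      nodes <- as.character(nodes)
      missing <- setdiff(unique(as.vector(lab)), nodes)
      if (length(missing)) {
        stop("edge endpoints not declared in `nodes`: ",
             paste(utils::head(missing, 5L), collapse = ", "))
      }
    }
    idx <- matrix(match(as.vector(lab), nodes), ncol = 2L)
  }
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node labels")
  if (is.null(order_index)) order_index <- seq_along(nodes)
  order_index <- as.integer(order_index)
  if (length(order_index) != length(nodes)) {
    stop("`order_index` must have one entry per node")
  }
  net <- structure(
    list(nodes = nodes, edges = idx, order_index = order_index),
    class = "directed_network"
  )
  validate_network(net)
  net
}

validate_network <- function(net) {
  idx <- net$edges
  if (nrow(idx)) {
    loops <- which(idx[, 1L] == idx[, 2L])
    if (length(loops)) {
      stop("self-loops are not allowed: ",
           paste(net$nodes[idx[loops, 1L]], collapse = ", "))
    }
    key <- paste(idx[, 1L], idx[, 2L])
    dup <- which(duplicated(key))
    if (length(dup)) {
      stop("duplicate edges: ",
           paste(net$nodes[idx[dup, 1L]], "->", net$nodes[idx[dup, 2L]],
                 collapse = "; "))
    }
  }
  invisible(net)
}

#' @rdname directed_network
#' @param net a `directed_network`
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname directed_network
#' @export
n_edges <- function(net) nrow(net$edges)

#' @export
print.directed_network <- function(x, ...) {
  cat("directed_network:", n_nodes(x), "nodes,", n_edges(x), "edges\n")
  invisible(x)
}

#' Adjacency-matrix view of a network
#'
#' @param net a `directed_network`
#' @return square 0/1 matrix in declared node order, dimnames = node labels;
#'   entry `[i, j] = 1` iff the directed edge i -> j exists.
#' @export
as_adjacency <- function(net) {
  n <- n_nodes(net)
  a <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  if (n_edges(net)) a[net$edges] <- 1L
  a
}

#' Edge list with node labels
#'
#' @param net a `directed_network`
#' @return data frame with character columns `source`, `target`.
#' @export
edge_labels <- function(net) {
  data.frame(
    source = net$nodes[net$edges[, 1L]],
    target = net$nodes[net$edges[, 2L]],
    stringsAsFactors = FALSE
  )
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    edge_labels(net), directed = TRUE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
}

#' Read a network from an edge-list TSV or adjacency CSV
#'
#' Edge-list files hold one `source<TAB>target` pair per line; blank lines
#' and lines starting with `#` are ignored, and node order follows first
#' appearance. Adjacency files are square 0/1 CSV matrices with a header row
#' and a leading column of node labels; node order follows row order.
#'
#' @param path file to read
#' @param format `"edge_list"` or `"adjacency"`
#' @return a validated [directed_network()]
#' @export
read_network <- function(path, format = c("edge_list", "adjacency")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edge_list") {
    lines <- readLines(path)
    keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
    if (!length(keep)) {
      stop("no edges found in ", path,
           " (empty-edge networks need the adjacency format)")
    }
    parts <- strsplit(lines[keep], "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad)) {
      stop("malformed edge-list row at line ", keep[bad[1L]], " of ", path,
           ": ", lines[keep[bad[1L]]])
    }
    em <- do.call(rbind, parts)
    directed_network(em)
  } else {
    df <- utils::read.csv(path, row.names = 1L, check.names = FALSE,
                          stringsAsFactors = FALSE)
    a <- as.matrix(df)
    if (nrow(a) != ncol(a)) stop("adjacency matrix must be square")
    if (!all(a %in% c(0, 1))) stop("adjacency entries must be 0 or 1")
    labels <- rownames(a)
    if (!identical(labels, colnames(a))) {
      stop("adjacency row and column labels must match")
    }
    idx <- which(a == 1, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    directed_network(matrix(as.integer(idx), ncol = 2L), nodes = labels)
  }
}

#' Write a network to an edge-list TSV or adjacency CSV
#'
#' `read_network(write_network(net, ...))` reproduces the node set, edge set
#' and node order exactly (for edge lists, node order is first-appearance
#' order of the written edges, so isolated nodes require the adjacency
#' format).
#'
#' @param net a `directed_network`
#' @param path output file
#' @param format `"edge_list"` or `"adjacency"`
#' @return `path`, invisibly
#' @export
write_network <- function(net, path, format = c("edge_list", "adjacency")) {
  format <- match.arg(format)
  if (format == "edge_list") {
    el <- edge_labels(net)
    writeLines(paste(el$source, el$target, sep = "\t"), con = path)
  } else {
    utils::write.csv(as_adjacency(net), file = path, quote = FALSE)
  }
  invisible(path)
}

#' Per-node degree accounting
#'
#' @param net a `directed_network`
#' @return data frame with columns `node`, `in_degree`, `out_degree`,
#'   `total_degree` in declared node order. The handshake identity
#'   `sum(in_degree) == sum(out_degree) == n_edges(net)` always holds.
#' @export
degrees <- function(net) {
  n <- n_nodes(net)
  data.frame(
    node = net$nodes,
    in_degree = tabulate(net$edges[, 2L], nbins = n),
    out_degree = tabulate(net$edges[, 1L], nbins = n),
    total_degree = tabulate(net$edges[, 1L], nbins = n) +
      tabulate(net$edges[, 2L], nbins = n),
    stringsAsFactors = FALSE
  )
}

#' Check that a network can host the communication model
#'
#' The random-walk routing requires every node to have at least one outgoing
#' edge (a served unit must be able to hop somewhere) and the model is only
#' interesting when every node can also receive (in-degree >= 1). Strong
#' connectivity is reported but not required: on a network that is not
#' strongly connected some units can never reach their destination, but they
#' are eventually ejected by the push-out buffers, so the model stays
#' well-defined.
#'
#' @param net a `directed_network`
#' @return list with `ok` (degree floor satisfied), `min_in`, `min_out`,
#'   `offenders` (data frame of violating nodes), `strongly_connected`.
#' @export
check_simulatable <- function(net) {
  d <- degrees(net)
  bad <- d[d$in_degree < 1L | d$out_degree < 1L, , drop = FALSE]
  sc <- if (n_nodes(net) <= 1L) TRUE else {
    igraph::is_connected(as_igraph(net), mode = "strong")
  }
  list(
    ok = nrow(bad) == 0L,
    min_in = if (nrow(d)) min(d$in_degree) else 0L,
    min_out = if (nrow(d)) min(d$out_degree) else 0L,
    offenders = bad,
    strongly_connected = sc
  )
}

# out-neighbour index lists (0-based) for the C++ engine
out_neighbours0 <- function(net) {
  n <- n_nodes(net)
  nb <- split(net$edges[, 2L] - 1L,
              factor(net$edges[, 1L], levels = seq_len(n)))
  lapply(nb, as.integer)
}
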