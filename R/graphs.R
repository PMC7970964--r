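#' Directed signed graphs
#'
#' The package's central graph container: a directed graph on `node_count`
#' nodes whose edges carry a sign (+1 activating / excitatory, -1 inhibiting)
#' and optionally a real weight. Nodes may be tagged with a functional role
#' (`input`, `hidden`, `output`, `sensory`, `muscle`).
#'
#' @param node_count Positive integer number of nodes.
#' @param edges Data frame with columns `from`, `to` (1-based node indices),
#'   `sign` (each exactly -1 or +1) and optionally `weight` (real; defaults
#'   to `sign` when missing).
#' @param node_roles Character vector of length `node_count` with values in
#'   `c("input", "hidden", "output", "sensory", "muscle")`, or `NULL` for
#'   all-`"hidden"`.
#' @return An object of class `directed_signed_graph` with elements
#'   `node_count`, `node_roles`, and `edges` (a data frame with columns
#'   `from`, `to`, `sign`, `weight`).
#' @examples
#' g <- directed_signed_graph(3, data.frame(from = c(1, 2), to = c(2, 3),
#'                                          sign = c(1, -1)))
#' mean_degree(g)
#' @export
directed_signed_graph <- function(node_count, edges = NULL, node_roles = NULL) {
  if (!is.numeric(node_count) || length(node_count) != 1L || node_count < 1 ||
      node_count != round(node_count)) {
    stop_invalid("node_count must be a positive integer")
  }
  node_count <- as.integer(node_count)
  if (is.null(edges)) {
    edges <- data.frame(from = integer(), to = integer(),
                        sign = numeric(), weight = numeric())
  }
  edges <- as.data.frame(edges)
  if (!all(c("from", "to", "sign") %in% names(edges))) {
    stop_invalid("edges must have columns from, to, sign")
  }
  if (is.null(edges$weight)) edges$weight <- as.numeric(edges$sign)
  edges <- edges[c("from", "to", "sign", "weight")]
  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)
  if (nrow(edges)) {
    if (any(edges$from < 1L | edges$from > node_count |
            edges$to < 1L | edges$to > node_count)) {
      stop_invalid("edge indices must lie in [1, node_count]")
    }
    if (!all(edges$sign %in% c(-1, 1))) {
      stop_invalid("every edge sign must be exactly -1 or +1")
    }
    if (anyDuplicated(edges[c("from", "to")])) {
      stop_invalid("duplicate (from, to) pairs are not allowed")
    }
  }
  if (is.null(node_roles)) node_roles <- rep("hidden", node_count)
  node_roles <- match.arg(node_roles,
                          c("input", "hidden", "output", "sensory", "muscle"),
                          several.ok = TRUE)
  if (length(node_roles) != node_count) {
    stop_invalid("node_roles must have length node_count")
  }
  structure(list(node_count = node_count, node_roles = node_roles,
                 edges = edges),
            class = "directed_signed_graph")
}

#' @export
print.directed_signed_graph <- function(x, ...) {
  cat(sprintf("<directed_signed_graph> %d nodes, %d edges (mean degree %.2f)\n",
              x$node_count, nrow(x$edges), mean_degree(x)))
  invisible(x)
}

#' Mean degree of a directed signed graph
#'
#' Edges per node: `|E| / n`, the quantity the package calls the average
#' connectivity `c`.
#' @param graph A [directed_signed_graph()].
#' @return A single real number.
#' @export
mean_degree <- function(graph) {
  nrow(graph$edges) / graph$node_count
}

as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = graph$node_count, directed = TRUE)
  if (nrow(graph$edges)) {
    g <- igraph::add_edges(g, rbind(graph$edges$from, graph$edges$to))
  }
  g
}

#' Fraction of nodes in the largest weakly connected component
#'
#' Treats every directed edge as undirected and reports the size of the
#' largest connected component divided by the node count. This is the
#' statistic `S` used to diagnose whether a sparsified network is still one
#' communicating system or has fallen apart into islands.
#'
#' @param graph A [directed_signed_graph()].
#' @return Real in (0, 1]: isolated nodes count as singleton components, so
#'   an edgeless graph returns `1 / node_count`.
#' @export
weakly_connected_fraction <- function(graph) {
  stopifnot(inherits(graph, "directed_signed_graph"))
  comp <- igraph::components(as_igraph(graph), mode = "weak")
  max(comp$csize) / graph$node_count
}

#' Graph summary metrics
#'
#' @param graph A [directed_signed_graph()].
#' @return A `graph_summary` list: `mean_degree`, `wcc_fraction`,
#'   `in_degree_sequence` and `out_degree_sequence` (sorted increasing),
#'   `edge_count`.
#' @export
graph_summary <- function(graph) {
  din <- tabulate(graph$edges$to, nbins = graph$node_count)
  dout <- tabulate(graph$edges$from, nbins = graph$node_count)
  structure(list(mean_degree = mean_degree(graph),
                 wcc_fraction = weakly_connected_fraction(graph),
                 in_degree_sequence = sort(din),
                 out_degree_sequence = sort(dout),
                 edge_count = nrow(graph$edges)),
            class = "graph_summary")
}

## Assign signs at neuron level: a fixed fraction of nodes is inhibitory and
## all of a node's out-edges inherit its sign.
.sign_edges_by_neuron <- function(edges, node_count, inhibitory_fraction) {
  n_inh <- round(inhibitory_fraction * node_count)
  inhibitory <- rep(FALSE, node_count)
  if (n_inh > 0) inhibitory[sample.int(node_count, n_inh)] <- TRUE
  edges$sign <- ifelse(inhibitory[edges$from], -1, 1)
  edges$weight <- as.numeric(edges$sign)
  edges
}

#' Random directed G(n, p) graph at a target mean degree
#'
#' Every ordered node pair, including self-loops (the graph is meant for
#' recurrent use), exists independently with probability `p = c / n`, giving
#' an expected mean degree of `c`. Signs are assigned per neuron: a fraction
#' `inhibitory_fraction` of nodes is marked inhibitory and all their
#' out-edges get sign -1.
#'
#' @param n Number of nodes.
#' @param c Target mean degree, `0 <= c <= n`.
#' @param seed Integer seed; identical seeds give identical edge lists.
#' @param inhibitory_fraction Fraction of inhibitory neurons (default 0.25,
#'   the midpoint of the 20--30% range used for biological networks).
#' @param loops Allow self-loops (default `TRUE`).
#' @return A [directed_signed_graph()].
#' @export
generate_gnp <- function(n, c, seed = NULL, inhibitory_fraction = 0.25,
                         loops = TRUE) {
  if (c < 0 || c > n) stop_invalid("c must lie in [0, n]")
  with_seed(seed, {
    p <- c / n
    n_pairs <- if (loops) n * n else n * (n - 1L)
    hit <- which(stats::runif(n_pairs) < p)
    if (loops) {
      from <- (hit - 1L) %% n + 1L
      to <- (hit - 1L) %/% n + 1L
    } else {
      # enumerate ordered pairs without the diagonal
      row <- (hit - 1L) %% (n - 1L) + 1L
      to <- (hit - 1L) %/% (n - 1L) + 1L
      from <- ifelse(row >= to, row + 1L, row)
    }
    edges <- data.frame(from = from, to = to,
                        sign = rep(1, length(from)),
                        weight = rep(1, length(from)))
    edges <- .sign_edges_by_neuron(edges, n, inhibitory_fraction)
    directed_signed_graph(n, edges)
  })
}

#' Directed small-world (Watts--Strogatz style) graph
#'
#' Builds a directed ring lattice in which every node sends an edge to its
#' `k / 2` nearest successors and `k / 2` nearest predecessors, then rewires
#' each edge's target independently with probability `beta` to a uniformly
#' chosen new target (no self-loops, no duplicate edges). Node and edge
#' counts are preserved under rewiring.
#'
#' @param n Number of nodes.
#' @param k Even out-degree of the initial lattice, `k < n`.
#' @param beta Rewiring probability in `[0, 1]` (default 0.1).
#' @param seed Integer seed.
#' @param inhibitory_fraction As in [generate_gnp()].
#' @return A [directed_signed_graph()] with exactly `n * k` edges.
#' @export
generate_small_world <- function(n, k, beta = 0.1, seed = NULL,
                                 inhibitory_fraction = 0.25) {
  if (k %% 2 != 0 || k >= n || k < 0) stop_invalid("k must be even and < n")
  if (beta < 0 || beta > 1) stop_invalid("beta must lie in [0, 1]")
  with_seed(seed, {
    half <- k %/% 2
    offs <- c(seq_len(half), -seq_len(half))
    from <- rep(seq_len(n), each = k)
    to <- ((from - 1L + rep(offs, n)) %% n) + 1L
    has_edge <- matrix(FALSE, n, n)
    has_edge[cbind(from, to)] <- TRUE
    rewire <- stats::runif(length(from)) < beta
    for (i in which(rewire)) {
      s <- from[i]
      candidates <- which(!has_edge[s, ])
      candidates <- setdiff(candidates, s)
      if (!length(candidates)) next
      new_t <- candidates[sample.int(length(candidates), 1L)]
      has_edge[s, to[i]] <- FALSE
      has_edge[s, new_t] <- TRUE
      to[i] <- new_t
    }
    edges <- data.frame(from = from, to = to, sign = 1, weight = 1)
    edges <- .sign_edges_by_neuron(edges, n, inhibitory_fraction)
    directed_signed_graph(n, edges)
  })
}

#' Diversity in-degree sequences
#'
#' Draws per-node in-degrees from the two-component normal mixtures that
#' define the dense- and sparse-diversity initializations: dense draws
#' `round(N(100, 10))` for 35% of nodes and `round(N(50, 5))` otherwise;
#' sparse draws `round(N(8, 2))` for 80% of nodes and `round(N(25, 5))`
#' otherwise. Draws are rounded to the nearest integer and clipped to
#' `[0, n - 1]`.
#'
#' @param kind `"dense"` or `"sparse"`.
#' @param n Number of nodes.
#' @param seed Integer seed.
#' @return Integer vector of length `n`.
#' @export
diversity_degree_sequence <- function(kind = c("dense", "sparse"), n,
                                      seed = NULL) {
  kind <- match.arg(kind)
  if (n < 1) stop_invalid("n must be >= 1")
  with_seed(seed, {
    params <- if (kind == "dense") {
      list(p = 0.35, mu = c(100, 50), sd = c(10, 5))
    } else {
      list(p = 0.80, mu = c(8, 25), sd = c(2, 5))
    }
    grp <- ifelse(stats::runif(n) < params$p, 1L, 2L)
    d <- round(stats::rnorm(n, params$mu[grp], params$sd[grp]))
    as.integer(pmin(pmax(d, 0), n - 1))
  })
}

#' Write / read a directed signed graph as a 4-column TSV edge list
#'
#' Columns are `from`, `to`, `sign`, `weight`. Node count and roles are kept
#' in `# node_count=` / `# roles=` header comment lines so the round trip is
#' lossless.
#' @param graph A [directed_signed_graph()].
#' @param path File path.
#' @return `write_edge_tsv` returns `path` invisibly; `read_edge_tsv`
#'   returns the graph.
#' @export
write_edge_tsv <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# node_count=%d", graph$node_count), con)
  writeLines(paste0("# roles=", paste(graph$node_roles, collapse = ",")), con)
  utils::write.table(graph$edges, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_tsv
#' @export
read_edge_tsv <- function(path) {
  header <- readLines(path, n = 2L)
  n <- as.integer(sub("# node_count=", "", header[1]))
  roles <- strsplit(sub("# roles=", "", header[2]), ",")[[1]]
  edges <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  directed_signed_graph(n, edges, roles)
}

#' Export a directed signed graph to GraphML
#'
#' @param graph A [directed_signed_graph()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  g <- as_igraph(graph)
  igraph::V(g)$role <- graph$node_roles
  if (nrow(graph$edges)) {
    igraph::E(g)$sign <- graph$edges$sign
    igraph::E(g)$weight <- graph$edges$weight
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Adjacency-matrix conversions
#'
#' `graph_to_adjacency` returns the signed weight matrix (entry `[i, j]` is
#' the weight of edge i -> j, 0 when absent); `graph_from_adjacency` is its
#' inverse, taking signs from the entries' signs.
#' @param graph A [directed_signed_graph()].
#' @return A `node_count` x `node_count` numeric matrix.
#' @export
graph_to_adjacency <- function(graph) {
  A <- matrix(0, graph$node_count, graph$node_count)
  if (nrow(graph$edges)) {
    A[cbind(graph$edges$from, graph$edges$to)] <-
      graph$edges$sign * abs(graph$edges$weight)
  }
  A
}

#' @rdname graph_to_adjacency
#' @param A Square numeric matrix.
#' @export
graph_from_adjacency <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  idx <- which(A != 0, arr.ind = TRUE)
  edges <- data.frame(from = idx[, 1], to = idx[, 2],
                      sign = sign(A[idx]), weight = abs(A[idx]))
  directed_signed_graph(nrow(A), edges)
}
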