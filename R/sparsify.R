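#' Ternary structure of a sparse network
#'
#' A `ternary_structure` holds, per connection block, a matrix over
#' \{-1, 0, +1\}: +1 an activating connection, -1 an inhibiting one, 0 no
#' connection. The total number of nonzero entries equals
#' `round(n_nodes * target_mean_degree)`.
#'
#' @param blocks List of matrices with entries in \{-1, 0, +1\}.
#' @param target_mean_degree The average connectivity `c` the structure was
#'   built for.
#' @param n_nodes Total node count of the owning architecture.
#' @return An object of class `ternary_structure`.
#' @export
ternary_structure <- function(blocks, target_mean_degree, n_nodes) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  for (b in blocks) {
    if (!all(b %in% c(-1, 0, 1))) {
      stop_invalid("ternary structure entries must be in {-1, 0, +1}")
    }
  }
  structure(list(blocks = blocks,
                 target_mean_degree = target_mean_degree,
                 n_nodes = as.integer(n_nodes)),
            class = "ternary_structure")
}

#' @export
print.ternary_structure <- function(x, ...) {
  nz <- sum(vapply(x$blocks, function(b) sum(b != 0), numeric(1)))
  cat(sprintf("<ternary_structure> %d blocks, %d active connections (c = %g, n = %d)\n",
              length(x$blocks), nz, x$target_mean_degree, x$n_nodes))
  invisible(x)
}

#' Number of active (nonzero) connections
#' @param structure A [ternary_structure()].
#' @return Integer count.
#' @export
structure_edge_count <- function(structure) {
  sum(vapply(structure$blocks, function(b) sum(b != 0), numeric(1)))
}

.infer_n_nodes <- function(blocks) {
  if (length(blocks) == 1L && nrow(blocks[[1]]) == ncol(blocks[[1]])) {
    return(nrow(blocks[[1]]))
  }
  dims_chain <- all(vapply(seq_len(length(blocks) - 1L), function(i) {
    ncol(blocks[[i]]) == nrow(blocks[[i + 1L]])
  }, logical(1)))
  square <- any(vapply(blocks, function(b) nrow(b) == ncol(b), logical(1)))
  if (dims_chain && !square) {
    return(nrow(blocks[[1]]) + sum(vapply(blocks, ncol, numeric(1))))
  }
  stop_invalid("cannot infer the total node count from these blocks; ",
               "pass n_nodes explicitly")
}

#' Sparsify dense weight blocks to a ternary structure
#'
#' Converts a dense network into a sparse signed graph by keeping the
#' `round(n_nodes * c)` globally strongest connections: all block entries
#' are ranked by absolute weight across blocks (ties broken by ascending
#' flat position, blocks in order), the top entries are retained with their
#' signs (+1 for positive weights, -1 for negative), and everything else
#' becomes 0. The threshold is thereby adjusted dynamically so the average
#' connectivity stays exactly `c`.
#'
#' @param weight_blocks List of real matrices (a model's connection blocks),
#'   or a single matrix.
#' @param c Target mean degree, `> 0` and such that `round(n_nodes * c)`
#'   does not exceed the total entry count.
#' @param n_nodes Total node count of the owning architecture. Inferred for
#'   a single square block (recurrent: `nrow`) or for a chain of
#'   non-square feed-forward blocks (`nrow(first) + sum(ncol)`), otherwise
#'   required.
#' @return A [ternary_structure()].
#' @export
sparsify_to_structure <- function(weight_blocks, c, n_nodes = NULL) {
  if (is.matrix(weight_blocks)) weight_blocks <- list(weight_blocks)
  stopifnot(is.list(weight_blocks), length(weight_blocks) >= 1L)
  if (!is.numeric(c) || length(c) != 1L || c <= 0) {
    stop_invalid("c must be a positive real")
  }
  if (is.null(n_nodes)) n_nodes <- .infer_n_nodes(weight_blocks)
  total <- sum(vapply(weight_blocks, length, numeric(1)))
  k <- round(n_nodes * c)
  if (k > total) {
    stop_invalid("round(n_nodes * c) = ", k, " exceeds the ", total,
                 " available entries")
  }
  flat <- unlist(lapply(weight_blocks, as.numeric), use.names = FALSE)
  if (sum(flat != 0) < k) {
    stop_degenerate("fewer than round(n_nodes * c) nonzero weights; ",
                    "cannot reach the target mean degree")
  }
  keep <- order_by_magnitude(flat)[seq_len(k)]
  tern <- numeric(total)
  tern[keep] <- sign(flat[keep])
  offset <- 0L
  blocks <- lapply(unname(weight_blocks), function(b) {
    m <- matrix(tern[offset + seq_along(b)], nrow(b), ncol(b))
    offset <<- offset + length(b)
    m
  })
  ternary_structure(blocks, c, n_nodes)
}

#' Interpret a ternary structure as a directed signed graph
#'
#' Nodes are numbered by stacking the block layers: for a feed-forward
#' chain, layer 0 rows first, then each block's columns; for a single
#' square block the nodes are its rows. Used for connectivity analyses of
#' sparsified networks.
#' @param structure A [ternary_structure()].
#' @return A [directed_signed_graph()] on `structure$n_nodes` nodes.
#' @export
structure_to_graph <- function(structure) {
  blocks <- structure$blocks
  # a square first block is read as a recurrent state layer only when the
  # declared node count says so; otherwise the blocks form a plain chain
  recur_total <- nrow(blocks[[1]]) +
    sum(vapply(blocks[-1L], ncol, numeric(1)))
  first_square <- nrow(blocks[[1]]) == ncol(blocks[[1]]) &&
    structure$n_nodes == recur_total
  # layer offsets: a leading square block maps a layer onto itself
  # (recurrent state), every further block's columns open a new layer
  row_offs <- integer(length(blocks))
  col_offs <- integer(length(blocks))
  next_off <- nrow(blocks[[1]])
  for (i in seq_along(blocks)) {
    row_offs[i] <- if (i == 1L) 0L else col_offs[i - 1L]
    if (i == 1L && first_square) {
      col_offs[i] <- 0L
    } else {
      col_offs[i] <- next_off
      next_off <- next_off + ncol(blocks[[i]])
    }
  }
  edges <- list()
  for (i in seq_along(blocks)) {
    idx <- which(blocks[[i]] != 0, arr.ind = TRUE)
    if (!nrow(idx)) next
    edges[[length(edges) + 1L]] <- data.frame(
      from = row_offs[i] + idx[, 1],
      to = col_offs[i] + idx[, 2],
      sign = blocks[[i]][idx])
  }
  edges <- if (length(edges)) do.call(rbind, edges) else NULL
  directed_signed_graph(structure$n_nodes, edges)
}

#' Count of positions whose ternary category differs ("odd edges")
#'
#' Compares two ternary structures position by position over all blocks and
#' counts positions whose category in \{-1, 0, +1\} differs.
#' @param structA,structB [ternary_structure()] objects with identical
#'   block shapes.
#' @return List with `count` and `fraction` (count over total positions).
#' @export
odd_edge_count <- function(structA, structB) {
  a <- structA$blocks; b <- structB$blocks
  if (length(a) != length(b) ||
      !all(mapply(function(x, y) all(dim(x) == dim(y)), a, b))) {
    stop_config("structures have mismatching block shapes")
  }
  total <- sum(vapply(a, length, numeric(1)))
  count <- sum(mapply(function(x, y) sum(x != y), a, b))
  list(count = as.integer(count), fraction = count / total)
}
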