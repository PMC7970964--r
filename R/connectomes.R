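#' Connectome graphs
#'
#' Container for a micro-connectome at the C. elegans scale: a weighted
#' directed graph among `neuron_count` neurons (synapse counts as weights),
#' plus weighted directed edges from neurons to `muscle_count` muscle
#' attachment points, with per-neuron sensory flags. Connection signs
#' (excitatory/inhibitory) are not part of the measured data and are
#' assigned afterwards with [assign_connection_signs()].
#'
#' @param neuron_edges Data frame `from`, `to`, `weight` (weights >= 0)
#'   among neurons.
#' @param muscle_edges Data frame `from` (neuron), `to` (muscle index),
#'   `weight`.
#' @param neuron_count,muscle_count Node counts.
#' @param sensory_flags Logical vector of length `neuron_count`.
#' @param signs Optional numeric vector of per-neuron signs (+1/-1) set by
#'   [assign_connection_signs()].
#' @return Object of class `connectome_graph`.
#' @export
connectome_graph <- function(neuron_count, muscle_count, neuron_edges,
                             muscle_edges, sensory_flags = NULL,
                             signs = NULL) {
  neuron_count <- as.integer(neuron_count)
  muscle_count <- as.integer(muscle_count)
  neuron_edges <- as.data.frame(neuron_edges)
  muscle_edges <- as.data.frame(muscle_edges)
  if (nrow(neuron_edges) && any(neuron_edges$weight < 0) ||
      nrow(muscle_edges) && any(muscle_edges$weight < 0)) {
    stop_format("connectome edge weights must be non-negative")
  }
  if (is.null(sensory_flags)) sensory_flags <- rep(FALSE, neuron_count)
  structure(list(neuron_count = neuron_count,
                 muscle_count = muscle_count,
                 neuron_edges = neuron_edges,
                 muscle_edges = muscle_edges,
                 sensory_flags = sensory_flags,
                 signs = signs),
            class = "connectome_graph")
}

#' @export
print.connectome_graph <- function(x, ...) {
  cat(sprintf(paste0("<connectome_graph> %d neurons (%d sensory), %d synapse",
                     " edges; %d muscles, %d muscle edges\n"),
              x$neuron_count, sum(x$sensory_flags), nrow(x$neuron_edges),
              x$muscle_count, nrow(x$muscle_edges)))
  if (nrow(x$neuron_edges) + nrow(x$muscle_edges) == 0L) {
    cat("  (empty connectome)\n")
  }
  invisible(x)
}

#' Load a micro-connectome from CSV adjacency matrices
#'
#' Reads the neuron-to-neuron and neuron-to-muscle adjacency matrices
#' (entry `[i, j]` = synapse count of connection i -> j; 0 = no connection)
#' and separates them into the two edge blocks of a [connectome_graph()].
#'
#' @param neuron_csv Path to the square neuron adjacency CSV.
#' @param muscle_csv Path to the rectangular neuron-by-muscle CSV.
#' @param sensory_flags Optional logical vector marking sensory neurons.
#' @param header Whether the CSVs carry a header row (default `FALSE`).
#' @return A [connectome_graph()].
#' @export
load_celegans_connectome <- function(neuron_csv, muscle_csv,
                                     sensory_flags = NULL, header = FALSE) {
  nn <- as.matrix(utils::read.csv(neuron_csv, header = header))
  nm <- as.matrix(utils::read.csv(muscle_csv, header = header))
  if (nrow(nn) != ncol(nn)) stop_format("neuron matrix must be square")
  if (nrow(nm) != nrow(nn)) {
    stop_format("muscle matrix must have one row per neuron")
  }
  if (any(nn < 0) || any(nm < 0)) stop_format("negative synapse counts")
  idx <- which(nn != 0, arr.ind = TRUE)
  neuron_edges <- data.frame(from = idx[, 1], to = idx[, 2], weight = nn[idx])
  idx <- which(nm != 0, arr.ind = TRUE)
  muscle_edges <- data.frame(from = idx[, 1], to = idx[, 2], weight = nm[idx])
  connectome_graph(nrow(nn), ncol(nm), neuron_edges, muscle_edges,
                   sensory_flags = sensory_flags)
}

#' Write a connectome to CSV adjacency matrices
#' @param connectome A [connectome_graph()].
#' @param neuron_csv,muscle_csv Output paths.
#' @return Invisibly, the two paths.
#' @export
write_celegans_connectome <- function(connectome, neuron_csv, muscle_csv) {
  nn <- matrix(0, connectome$neuron_count, connectome$neuron_count)
  ne <- connectome$neuron_edges
  if (nrow(ne)) nn[cbind(ne$from, ne$to)] <- ne$weight
  nm <- matrix(0, connectome$neuron_count, connectome$muscle_count)
  me <- connectome$muscle_edges
  if (nrow(me)) nm[cbind(me$from, me$to)] <- me$weight
  utils::write.table(nn, neuron_csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(nm, muscle_csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(c(neuron_csv, muscle_csv))
}

#' Generate a synthetic connectome with prescribed counts
#'
#' Random stand-in emulating the published C. elegans statistics: exactly
#' `synapse_edges` directed neuron-to-neuron edges (no self-connections),
#' `muscle_edges` neuron-to-muscle edges, integer synapse-count weights
#' drawn from a heavy-tailed distribution (`1 + Geom(geom_prob)`), and a
#' random subset of `sensory_count` neurons flagged sensory.
#'
#' @param neuron_count,sensory_count,muscle_count,synapse_edges,muscle_edges
#'   Target counts; defaults mirror the male C. elegans chemical-synapse
#'   dataset (369 neurons, 136 sensory, 134 muscles, 3888 synapse edges,
#'   1018 muscle edges).
#' @param geom_prob Success probability of the geometric weight tail
#'   (smaller = heavier tail; default 0.3).
#' @param seed Integer seed.
#' @return A [connectome_graph()].
#' @export
generate_synthetic_connectome <- function(neuron_count = 369L,
                                          sensory_count = 136L,
                                          muscle_count = 134L,
                                          synapse_edges = 3888L,
                                          muscle_edges = 1018L,
                                          geom_prob = 0.3, seed = NULL) {
  if (synapse_edges > neuron_count * (neuron_count - 1L)) {
    stop_invalid("synapse_edges exceeds the number of ordered neuron pairs")
  }
  if (muscle_edges > neuron_count * muscle_count) {
    stop_invalid("muscle_edges exceeds the neuron x muscle capacity")
  }
  if (sensory_count > neuron_count) {
    stop_invalid("sensory_count exceeds neuron_count")
  }
  with_seed(seed, {
    pick <- sample.int(neuron_count * (neuron_count - 1L), synapse_edges)
    row <- (pick - 1L) %% (neuron_count - 1L) + 1L
    to <- (pick - 1L) %/% (neuron_count - 1L) + 1L
    from <- ifelse(row >= to, row + 1L, row)
    ne <- data.frame(from = from, to = to,
                     weight = 1L + stats::rgeom(synapse_edges, geom_prob))
    pick <- sample.int(neuron_count * muscle_count, muscle_edges)
    me <- data.frame(from = (pick - 1L) %% neuron_count + 1L,
                     to = (pick - 1L) %/% neuron_count + 1L,
                     weight = 1L + stats::rgeom(muscle_edges, geom_prob))
    flags <- rep(FALSE, neuron_count)
    flags[sample.int(neuron_count, sensory_count)] <- TRUE
    connectome_graph(neuron_count, muscle_count, ne, me, sensory_flags = flags)
  })
}

#' Assign excitatory/inhibitory signs at the neuron level
#'
#' Draws one inhibitory fraction `f ~ U(range[1], range[2])`, marks
#' `round(f * neuron_count)` randomly chosen neurons inhibitory, and gives
#' every out-edge of an inhibitory neuron sign -1 and every other edge +1.
#' The 20--30% default range follows measured mammalian values, adopted in
#' the absence of sign information in the connectome data itself.
#'
#' @param connectome A [connectome_graph()].
#' @param inhibitory_fraction_range Length-2 numeric range (default
#'   `c(0.20, 0.30)`).
#' @param seed Integer seed.
#' @param level `"neuron"` (default; all out-edges of a neuron share its
#'   sign) or `"edge"` (signs drawn independently per edge).
#' @return The connectome with a `signs` vector (per neuron, or per edge
#'   stored on the edge tables when `level = "edge"`).
#' @export
assign_connection_signs <- function(connectome,
                                    inhibitory_fraction_range = c(0.20, 0.30),
                                    seed = NULL, level = c("neuron", "edge")) {
  level <- match.arg(level)
  if (nrow(connectome$neuron_edges) + nrow(connectome$muscle_edges) == 0L) {
    warning("empty connectome: no signs to assign")
    return(connectome)
  }
  with_seed(seed, {
    f <- stats::runif(1, inhibitory_fraction_range[1],
                      inhibitory_fraction_range[2])
    if (level == "neuron") {
      n_inh <- round(f * connectome$neuron_count)
      s <- rep(1, connectome$neuron_count)
      if (n_inh > 0) s[sample.int(connectome$neuron_count, n_inh)] <- -1
      connectome$signs <- s
      connectome$neuron_edges$sign <- s[connectome$neuron_edges$from]
      connectome$muscle_edges$sign <- s[connectome$muscle_edges$from]
    } else {
      connectome$neuron_edges$sign <-
        ifelse(stats::runif(nrow(connectome$neuron_edges)) < f, -1, 1)
      connectome$muscle_edges$sign <-
        ifelse(stats::runif(nrow(connectome$muscle_edges)) < f, -1, 1)
      connectome$signs <- NULL
    }
    connectome$inhibitory_fraction <- f
    connectome
  })
}

#' Threshold and direct a macro-connectome matrix
#'
#' Takes a symmetric weighted region-by-region connectivity matrix, keeps
#' the strongest undirected links until the target mean degree is reached
#' (weights are used only for this ordering and then discarded), and turns
#' each retained undirected link into a single directed signed edge with
#' direction and sign each chosen uniformly at random.
#'
#' @param matrix Square symmetric numeric matrix (or path to a CSV).
#' @param target_mean_degree Desired mean degree `c` (default 22).
#' @param seed Integer seed.
#' @param edge_convention `"one_directed"` (default): keep
#'   `round(n * c) / 2` undirected links, each becoming one directed edge;
#'   `"full"`: keep `round(n * c)` undirected links. Both readings of the
#'   published edge count are supported.
#' @return A [directed_signed_graph()].
#' @export
preprocess_human_connectome <- function(matrix, target_mean_degree = 22,
                                        seed = NULL,
                                        edge_convention = c("one_directed",
                                                            "full")) {
  edge_convention <- match.arg(edge_convention)
  if (is.character(matrix)) {
    matrix <- as.matrix(utils::read.csv(matrix, header = FALSE))
  }
  if (nrow(matrix) != ncol(matrix) || !isTRUE(all.equal(matrix, t(matrix)))) {
    stop_format("input must be a square symmetric matrix")
  }
  n <- nrow(matrix)
  ut <- which(upper.tri(matrix))
  w <- matrix[ut]
  n_links <- round(n * target_mean_degree)
  if (edge_convention == "one_directed") n_links <- round(n_links / 2)
  if (n_links > length(ut)) stop_invalid("target mean degree too large")
  keep <- ut[order_by_magnitude(w)[seq_len(n_links)]]
  i <- (keep - 1L) %% n + 1L
  j <- (keep - 1L) %/% n + 1L
  with_seed(seed, {
    flip <- stats::runif(n_links) < 0.5
    from <- ifelse(flip, j, i)
    to <- ifelse(flip, i, j)
    sgn <- ifelse(stats::runif(n_links) < 0.5, -1, 1)
    directed_signed_graph(n, data.frame(from = from, to = to, sign = sgn,
                                        weight = 1))
  })
}

#' Generate a synthetic macro-connectome matrix
#'
#' Symmetric weighted 177-region stand-in for a functional connectivity
#' matrix: entries are absolute correlations decaying with a latent
#' community structure, suitable for thresholding to a mean degree near 22.
#' @param n Region count (default 177).
#' @param seed Integer seed.
#' @return An `n` x `n` symmetric numeric matrix with zero diagonal.
#' @export
generate_synthetic_human_matrix <- function(n = 177L, seed = NULL) {
  with_seed(seed, {
    z <- matrix(stats::rnorm(n * 4L), n, 4L)
    m <- abs(tcrossprod(z)) / 4
    m <- (m + t(m)) / 2
    diag(m) <- 0
    m
  })
}
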