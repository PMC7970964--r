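#' Connectome spec bundles
#'
#' A spec bundle packages everything needed to build a trainable model from
#' a biological (or synthetic) connectome: the [arch_feed_forward()] /
#' [arch_recurrent()] architecture, the [ternary_structure()] carrying the
#' signed wiring pattern (the mask of the trainable blocks), and the fixed
#' random input encoder. The connectome's synapse-count weights are used
#' only for ordering and sign bookkeeping; trained weights are always
#' re-initialized, because the native values span an unusable numeric range
#' and carry no inhibition information.
#'
#' @param architecture A `layered_architecture`.
#' @param structure A [ternary_structure()] whose blocks match the
#'   architecture's structural blocks.
#' @param encoder Fixed encoder matrix (`encoder_dim` x `encoder_width`) or
#'   `NULL`.
#' @param provenance One of `"celegans"`, `"celegans_lenet"`,
#'   `"celegans_gnp_reference"`, `"human_connectome"`, `"synthetic"`.
#' @return Object of class `connectome_spec_bundle`.
#' @export
connectome_spec_bundle <- function(architecture, structure, encoder = NULL,
                                   provenance = "synthetic") {
  provenance <- match.arg(provenance,
                          c("celegans", "celegans_lenet",
                            "celegans_gnp_reference", "human_connectome",
                            "synthetic"))
  struct_blocks <- which(architecture$blocks$structural)
  if (length(structure$blocks) != length(struct_blocks)) {
    stop_config("structure block count does not match architecture")
  }
  for (i in seq_along(struct_blocks)) {
    bi <- struct_blocks[i]
    if (nrow(structure$blocks[[i]]) != architecture$blocks$nrow[bi] ||
        ncol(structure$blocks[[i]]) != architecture$blocks$ncol[bi]) {
      stop_config("structure block ", i, " shape mismatch")
    }
  }
  if (!is.null(encoder)) {
    stopifnot(nrow(encoder) == architecture$encoder_dim,
              ncol(encoder) == architecture$encoder_width)
  }
  structure(list(architecture = architecture, structure = structure,
                 encoder = encoder, provenance = provenance),
            class = "connectome_spec_bundle")
}

#' @export
print.connectome_spec_bundle <- function(x, ...) {
  cat(sprintf("<connectome_spec_bundle> %s: %d active connections\n",
              x$provenance, structure_edge_count(x$structure)))
  print(x$architecture)
  invisible(x)
}

.random_encoder <- function(dim_in, dim_out, range = 0.05) {
  matrix(stats::runif(dim_in * dim_out, -range, range), dim_in, dim_out)
}

.connectome_sign_blocks <- function(connectome) {
  n_edges <- nrow(connectome$neuron_edges) + nrow(connectome$muscle_edges)
  if (n_edges > 0L && is.null(connectome$neuron_edges$sign) &&
      is.null(connectome$muscle_edges$sign)) {
    stop_config("connectome has no signs; run assign_connection_signs() first")
  }
  nn <- matrix(0, connectome$neuron_count, connectome$neuron_count)
  ne <- connectome$neuron_edges
  if (nrow(ne)) nn[cbind(ne$from, ne$to)] <- ne$sign
  nm <- matrix(0, connectome$neuron_count, connectome$muscle_count)
  me <- connectome$muscle_edges
  if (nrow(me)) nm[cbind(me$from, me$to)] <- me$sign
  list(neuron = nn, muscle = nm)
}

#' Recurrent model specification from a micro-connectome
#'
#' Builds the recurrent biological model: the image input is encoded by a
#' fixed random U(-0.05, 0.05) matrix onto the sensory neurons, which sit
#' inside a tanh-activated recurrent layer over all neurons whose wiring
#' mask is the neuron adjacency; the state is mapped onto the tanh muscle
#' attachment points through the (masked) muscle adjacency; the muscle
#' outputs are decoded by a dense trainable softmax layer to 10 classes.
#'
#' @param connectome A signed [connectome_graph()] (signs are assigned with
#'   the default 20--30% inhibitory-neuron range if missing).
#' @param seed Integer seed for the encoder (and sign assignment if needed).
#' @param n_classes Output classes (default 10).
#' @param input_dim Raw input dimension (default 784).
#' @return A [connectome_spec_bundle()].
#' @export
celegans_recurrent_spec <- function(connectome, seed = NULL, n_classes = 10L,
                                    input_dim = 784L) {
  if (is.null(connectome$neuron_edges$sign)) {
    connectome <- assign_connection_signs(connectome, seed = seed)
  }
  sensory <- which(connectome$sensory_flags)
  if (!length(sensory)) stop_config("connectome has no sensory neurons")
  sgn <- .connectome_sign_blocks(connectome)
  arch <- arch_recurrent(
    state_size = connectome$neuron_count,
    input_index = sensory,
    post_layers = list(
      list(size = connectome$muscle_count, activation = "tanh",
           structural = TRUE),
      list(size = as.integer(n_classes), activation = "softmax",
           structural = FALSE)),
    encoder_dim = as.integer(input_dim),
    encoder_width = length(sensory),
    reserved_outputs = 0L)
  n_nodes <- connectome$neuron_count + connectome$muscle_count
  c_eff <- (nrow(connectome$neuron_edges) + nrow(connectome$muscle_edges)) /
    n_nodes
  struct <- ternary_structure(list(sgn$neuron, sgn$muscle), c_eff, n_nodes)
  enc <- with_seed(seed, .random_encoder(input_dim, length(sensory)))
  connectome_spec_bundle(arch, struct, enc, "celegans")
}

#' Distance of every neuron to the nearest muscle output
#'
#' Directed BFS distance: a neuron directly innervating a muscle has
#' distance 1; unreachable neurons get `Inf`.
#' @param connectome A [connectome_graph()].
#' @return Numeric vector of length `neuron_count`.
#' @export
distance_to_output <- function(connectome) {
  n <- connectome$neuron_count
  m <- connectome$muscle_count
  g <- igraph::make_empty_graph(n + m, directed = TRUE)
  if (nrow(connectome$neuron_edges)) {
    g <- igraph::add_edges(g, rbind(connectome$neuron_edges$from,
                                    connectome$neuron_edges$to))
  }
  if (nrow(connectome$muscle_edges)) {
    g <- igraph::add_edges(g, rbind(connectome$muscle_edges$from,
                                    n + connectome$muscle_edges$to))
  }
  d <- igraph::distances(g, v = seq_len(n), to = n + seq_len(m),
                         mode = "out")
  apply(d, 1, min)
}

#' Feed-forward model specification from a micro-connectome
#'
#' Flattens the connectome into a layered feed-forward network by the
#' minimal directed distance of every neuron to a muscle output: neurons at
#' distance 1 form the deepest hidden layer (feeding the muscles), distance
#' 2 the next, and all neurons at distance >= `n_hidden` are merged into
#' the layer farthest from the output. Neurons that cannot reach any muscle
#' are dropped. Only connectome edges between consecutive layers are kept
#' in the masks. Encoded inputs are injected at every layer: each surviving
#' sensory neuron receives its encoder column wherever it was binned.
#' Hidden layers are relu, muscles tanh, followed by a dense softmax decode
#' to `n_classes`.
#'
#' @inheritParams celegans_recurrent_spec
#' @param n_hidden Number of hidden (neuron) layers (default 3, giving a
#'   4-layer model including the muscle layer).
#' @return A [connectome_spec_bundle()]; attribute `dropped_nodes` carries
#'   the count of unreachable neurons.
#' @export
celegans_lenet_spec <- function(connectome, seed = NULL, n_hidden = 3L,
                                n_classes = 10L, input_dim = 784L) {
  if (is.null(connectome$neuron_edges$sign)) {
    connectome <- assign_connection_signs(connectome, seed = seed)
  }
  d <- distance_to_output(connectome)
  dropped <- which(!is.finite(d))
  if (length(dropped) == connectome$neuron_count) {
    stop_config("no neuron reaches a muscle output; connectome unusable")
  }
  # distance 1 -> layer n_hidden (deepest), distance >= n_hidden -> layer 1
  layer_of <- pmax(n_hidden + 1L - pmin(d, n_hidden), 1L)
  layer_of[dropped] <- NA_integer_
  layers <- lapply(seq_len(n_hidden), function(l) which(layer_of == l))
  # layers left empty by the distance distribution are dropped, keeping
  # the depth order; n_hidden is an upper bound, not a promise
  keep_layers <- lengths(layers) > 0L
  layers <- layers[keep_layers]
  n_hidden <- length(layers)
  if (n_hidden == 0L) stop_config("no neuron reaches a muscle output")
  layer_of <- match(layer_of, which(keep_layers))
  sizes <- lengths(layers)
  sgn <- .connectome_sign_blocks(connectome)
  blocks <- vector("list", n_hidden)  # hidden_l -> hidden_{l+1}, last -> muscle
  for (l in seq_len(n_hidden - 1L)) {
    blocks[[l]] <- sgn$neuron[layers[[l]], layers[[l + 1L]], drop = FALSE]
  }
  blocks[[n_hidden]] <- sgn$muscle[layers[[n_hidden]], , drop = FALSE]
  sensory <- which(connectome$sensory_flags)
  injections <- lapply(seq_len(n_hidden), function(l) {
    in_layer <- intersect(layers[[l]], sensory)
    if (!length(in_layer)) return(NULL)
    cbind(encoder_column = match(in_layer, sensory),
          unit_column = match(in_layer, layers[[l]]))
  })
  injections <- c(injections, list(NULL, NULL))  # muscle + decode layers
  arch <- arch_feed_forward(
    layer_sizes = c(0L, sizes, connectome$muscle_count,
                    as.integer(n_classes)),
    activations = c(rep("relu", n_hidden), "tanh", "softmax"),
    injections = injections,
    encoder_dim = as.integer(input_dim),
    encoder_width = length(sensory),
    structural = c(rep(TRUE, n_hidden + 1L), FALSE),
    node_count = sum(sizes) + connectome$muscle_count)
  n_nodes <- sum(sizes) + connectome$muscle_count
  n_edges <- sum(vapply(blocks, function(b) sum(b != 0), numeric(1)))
  struct <- ternary_structure(c(list(matrix(0, 0L, sizes[1L])), blocks),
                              n_edges / n_nodes, n_nodes)
  enc <- with_seed(seed, .random_encoder(input_dim, length(sensory)))
  out <- connectome_spec_bundle(arch, struct, enc, "celegans_lenet")
  attr(out, "dropped_nodes") <- length(dropped)
  attr(out, "layer_assignment") <- layer_of
  out
}

#' Random reference for the recurrent connectome model
#'
#' Keeps the muscle block verbatim but replaces the neuron-to-neuron wiring
#' with a directed G(n, p) draw whose expected edge count matches the
#' source connectome. Signs of the random edges follow the connectome's
#' per-neuron sign assignment.
#'
#' @inheritParams celegans_recurrent_spec
#' @return A [connectome_spec_bundle()] with provenance
#'   `"celegans_gnp_reference"`.
#' @export
celegans_gnp_reference_spec <- function(connectome, seed = NULL,
                                        n_classes = 10L, input_dim = 784L) {
  if (is.null(connectome$neuron_edges$sign)) {
    connectome <- assign_connection_signs(connectome, seed = seed)
  }
  n <- connectome$neuron_count
  c_nn <- nrow(connectome$neuron_edges) / n
  rnd <- with_seed(seed, {
    g <- generate_gnp(n, c_nn, seed = NULL, loops = FALSE)
    g
  })
  ne <- rnd$edges
  s <- if (!is.null(connectome$signs)) connectome$signs else rep(1, n)
  ne$sign <- s[ne$from]
  rnd_conn <- connectome_graph(n, connectome$muscle_count,
                               data.frame(from = ne$from, to = ne$to,
                                          weight = 1, sign = ne$sign),
                               connectome$muscle_edges,
                               sensory_flags = connectome$sensory_flags,
                               signs = s)
  out <- celegans_recurrent_spec(rnd_conn, seed = seed,
                                 n_classes = n_classes,
                                 input_dim = input_dim)
  out$provenance <- "celegans_gnp_reference"
  out
}

#' Recurrent model specification from a macro-connectome graph
#'
#' Wraps a thresholded, directed and signed region-level graph (from
#' [preprocess_human_connectome()]) as an encoded recurrent architecture:
#' all regions are input neurons fed through a fixed random encoder, with a
#' dense softmax readout.
#'
#' @param graph A [directed_signed_graph()].
#' @param seed Integer seed for the encoder.
#' @param n_classes,input_dim As in [celegans_recurrent_spec()].
#' @return A [connectome_spec_bundle()] with provenance
#'   `"human_connectome"`.
#' @export
human_connectome_spec <- function(graph, seed = NULL, n_classes = 10L,
                                  input_dim = 784L) {
  n <- graph$node_count
  A <- graph_to_adjacency(graph)
  arch <- arch_recurrent(n, input_index = seq_len(n),
                         post_layers = list(list(size = as.integer(n_classes),
                                                 activation = "softmax",
                                                 structural = FALSE)),
                         encoder_dim = as.integer(input_dim),
                         encoder_width = n, reserved_outputs = 0L)
  struct <- ternary_structure(list(sign(A)), mean_degree(graph), n)
  enc <- with_seed(seed, .random_encoder(input_dim, n))
  connectome_spec_bundle(arch, struct, enc, "human_connectome")
}

#' Save / load a spec bundle as plain-text artifacts
#'
#' Writes `architecture.json` (shape metadata), one `structure_<i>.csv` per
#' block, and `encoder.csv` into `dir`.
#' @param bundle A [connectome_spec_bundle()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_spec_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arch <- bundle$architecture
  meta <- list(kind = arch$kind, provenance = bundle$provenance,
               node_count = arch$node_count,
               target_mean_degree = bundle$structure$target_mean_degree,
               recurrent_steps = arch$recurrent_steps,
               blocks = arch$blocks)
  jsonlite::write_json(meta, file.path(dir, "architecture.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(bundle$structure$blocks)) {
    utils::write.table(bundle$structure$blocks[[i]],
                       file.path(dir, sprintf("structure_%d.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(bundle$encoder)) {
    utils::write.table(bundle$encoder, file.path(dir, "encoder.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
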