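#' Layered architecture specifications
#'
#' An architecture describes the shapes of a trainable network: either a
#' feed-forward stack of dense layers or a recurrent state layer iterated
#' for a fixed number of steps with constant input injection, followed by a
#' chain of readout layers. Connection *blocks* are the weight matrices
#' between layers; blocks flagged `structural` are the ones that carry a
#' maskable wiring pattern and enter every graph-level computation
#' (sparsification, mean degree, possible-edge counts). A dense readout
#' bolted onto a recurrent network is not structural.
#'
#' @param layer_sizes Integer vector of layer sizes including input and
#'   output (feed-forward).
#' @param activations Character vector, one per non-input layer, values in
#'   `c("relu", "tanh", "softmax")`. Defaults to relu hidden layers and a
#'   softmax output.
#' @param injections Optional per-layer input injection map for feed-forward
#'   networks whose inputs enter at several depths: a list with one element
#'   per non-input layer, each `NULL` or a two-column matrix
#'   `(encoder_column, unit_column)` adding encoded input columns onto layer
#'   pre-activations.
#' @param encoder_dim Dimension of the raw input fed through the fixed
#'   random encoder (e.g. 784), or `NULL` when the first layer reads the raw
#'   input directly.
#' @param encoder_width Number of encoder output columns (e.g. 136 sensory
#'   neurons); required when `encoder_dim` is set.
#' @return An object of class `layered_architecture`.
#' @export
arch_feed_forward <- function(layer_sizes, activations = NULL,
                              injections = NULL, encoder_dim = NULL,
                              encoder_width = NULL, structural = NULL,
                              node_count = NULL) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L) stop_invalid("feed-forward needs >= 2 layers")
  # a zero-width first layer means the input enters only through per-layer
  # encoder injections (connectome-derived feed-forward models)
  if (any(layer_sizes[-1L] < 1L) || layer_sizes[1L] < 0L) {
    stop_invalid("layer sizes must be positive (first may be 0 with injections)")
  }
  K <- length(layer_sizes) - 1L
  if (is.null(activations)) {
    activations <- c(rep("relu", K - 1L), "softmax")
  }
  stopifnot(length(activations) == K,
            all(activations %in% c("relu", "tanh", "softmax")))
  if (is.null(structural)) structural <- rep(TRUE, K)
  blocks <- data.frame(
    name = paste0("w", seq_len(K)),
    nrow = layer_sizes[-length(layer_sizes)],
    ncol = layer_sizes[-1L],
    structural = structural)
  if (is.null(node_count)) node_count <- sum(layer_sizes)
  structure(list(kind = "feed_forward",
                 layer_sizes = layer_sizes,
                 activations = activations,
                 blocks = blocks,
                 injections = injections,
                 encoder_dim = encoder_dim,
                 encoder_width = encoder_width,
                 input_node_count = layer_sizes[1L],
                 output_node_count = layer_sizes[length(layer_sizes)],
                 node_count = as.integer(node_count),
                 recurrent_steps = NA_integer_),
            class = "layered_architecture")
}

#' @rdname arch_feed_forward
#' @param state_size Number of recurrent state neurons.
#' @param input_index State positions that receive the (possibly encoded)
#'   input added to their pre-activation at every step.
#' @param post_layers List of readout layers applied once after the last
#'   recurrent step, each a list with `size`, `activation`, and logical
#'   `structural` (masked biological block vs. dense trainable readout).
#' @param recurrent_steps Number of state-update steps (default 25).
#' @param reserved_outputs Number of state nodes considered pinned to the
#'   output role when counting free nodes (default 10 for a dense readout).
#' @export
arch_recurrent <- function(state_size, input_index,
                           post_layers = list(list(size = 10L,
                                                   activation = "softmax",
                                                   structural = FALSE)),
                           recurrent_steps = 25L, encoder_dim = NULL,
                           encoder_width = NULL, reserved_outputs = 10L) {
  state_size <- as.integer(state_size)
  if (recurrent_steps < 1L) stop_invalid("recurrent_steps must be >= 1")
  stopifnot(all(input_index >= 1L), all(input_index <= state_size))
  sizes <- vapply(post_layers, function(p) as.integer(p$size), integer(1))
  structural <- vapply(post_layers, function(p) isTRUE(p$structural), logical(1))
  blocks <- data.frame(
    name = c("w_state", paste0("w_post", seq_along(post_layers))),
    nrow = c(state_size, c(state_size, sizes)[seq_along(post_layers)]),
    ncol = c(state_size, sizes),
    structural = c(TRUE, structural))
  structure(list(kind = "recurrent",
                 state_size = state_size,
                 input_index = as.integer(input_index),
                 post_layers = post_layers,
                 blocks = blocks,
                 encoder_dim = encoder_dim,
                 encoder_width = encoder_width,
                 input_node_count = length(input_index),
                 output_node_count = sizes[length(sizes)],
                 node_count = state_size + sum(sizes[structural]),
                 reserved_outputs = as.integer(reserved_outputs),
                 recurrent_steps = as.integer(recurrent_steps)),
            class = "layered_architecture")
}

#' @export
print.layered_architecture <- function(x, ...) {
  if (x$kind == "feed_forward") {
    cat(sprintf("<layered_architecture> feed-forward %s\n",
                paste(x$layer_sizes, collapse = "-")))
  } else {
    cat(sprintf("<layered_architecture> recurrent %d (%d steps), readout %s\n",
                x$state_size, x$recurrent_steps,
                paste(vapply(x$post_layers, function(p) p$size, integer(1)),
                      collapse = "-")))
  }
  invisible(x)
}

#' Stock architectures
#'
#' Convenience constructors for the architectures used throughout:
#' `arch_lenet_300_100()` (784-300-100-10, relu hidden, softmax output,
#' 1194 nodes), `arch_lenet_4x300()` (784-300-300-300-300-10), and
#' `arch_recurrent_gnp(n)` — a tanh recurrent state layer of `n` neurons of
#' which the first `input_nodes` receive the raw input at every one of the
#' 25 steps, read out by a dense softmax layer of 10.
#' @return A `layered_architecture`.
#' @export
arch_lenet_300_100 <- function() arch_feed_forward(c(784L, 300L, 100L, 10L))

#' @rdname arch_lenet_300_100
#' @export
arch_lenet_4x300 <- function() {
  arch_feed_forward(c(784L, 300L, 300L, 300L, 300L, 10L))
}

#' @rdname arch_lenet_300_100
#' @param n State size (default 1194).
#' @param input_nodes Number of leading state nodes used as input neurons
#'   (default 784).
#' @export
arch_recurrent_gnp <- function(n = 1194L, input_nodes = 784L) {
  arch_recurrent(n, input_index = seq_len(input_nodes))
}

#' @rdname arch_lenet_300_100
#' @details `arch_recurrent_encoded(n)` mirrors the 177-node architecture:
#'   every neuron is an input neuron, fed by a fixed random 784-to-`n`
#'   encoder drawn from U(-0.05, 0.05), with a dense softmax readout.
#' @export
arch_recurrent_encoded <- function(n = 177L) {
  arch_recurrent(n, input_index = seq_len(n), encoder_dim = 784L,
                 encoder_width = as.integer(n), reserved_outputs = 0L)
}

#' Free-node counts of an architecture
#'
#' Free nodes are nodes not pinned to an input or output role; permuting
#' them yields isomorphic networks. For feed-forward architectures every
#' hidden layer is free; for recurrent architectures the free set is the
#' state layer minus its input neurons and minus the nodes reserved for the
#' readout.
#' @param arch A `layered_architecture`.
#' @return Integer vector of per-layer free-node counts.
#' @export
free_node_counts <- function(arch) {
  stopifnot(inherits(arch, "layered_architecture"))
  if (arch$kind == "feed_forward") {
    n <- length(arch$layer_sizes)
    as.integer(arch$layer_sizes[-c(1L, n)])
  } else {
    as.integer(max(0L, arch$state_size - arch$input_node_count -
                     arch$reserved_outputs))
  }
}
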