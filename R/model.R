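#' Trainable masked model state
#'
#' `build_model()` allocates the trainable state for an architecture or a
#' connectome spec bundle: per-block weight matrices (zero-initialized),
#' per-layer neuron offset vectors (always initialized to 0), and binary
#' masks aligned to the weight blocks. For a bare architecture the masks
#' are all ones (dense); for a bundle they are the nonzero pattern of its
#' ternary structure. Masked positions hold weight exactly 0 and never
#' receive updates.
#'
#' @param spec A `layered_architecture` or [connectome_spec_bundle()].
#' @param encoder Optional fixed encoder matrix for encoded architectures
#'   (taken from the bundle when building from one; drawn from
#'   U(-0.05, 0.05) with `seed` when needed and missing).
#' @param seed Seed used only if an encoder must be drawn.
#' @param apply_mask For bundles: use the structure as mask (default
#'   `TRUE`); set `FALSE` to get a dense model of the same shapes.
#' @return Object of class `model_state` with elements `architecture`,
#'   `weights`, `offsets`, `masks`, `encoder`, `init_tag`.
#' @export
build_model <- function(spec, encoder = NULL, seed = NULL,
                        apply_mask = TRUE) {
  bundle <- NULL
  if (inherits(spec, "connectome_spec_bundle")) {
    bundle <- spec
    arch <- spec$architecture
    if (is.null(encoder)) encoder <- spec$encoder
  } else if (inherits(spec, "layered_architecture")) {
    arch <- spec
  } else {
    stop_config("spec must be a layered_architecture or a spec bundle")
  }
  binfo <- arch$blocks
  weights <- masks <- vector("list", nrow(binfo))
  names(weights) <- names(masks) <- binfo$name
  for (i in seq_len(nrow(binfo))) {
    weights[[i]] <- matrix(0, binfo$nrow[i], binfo$ncol[i])
    masks[[i]] <- matrix(1, binfo$nrow[i], binfo$ncol[i])
  }
  if (!is.null(bundle) && apply_mask) {
    si <- which(binfo$structural)
    for (j in seq_along(si)) {
      masks[[si[j]]] <- abs(bundle$structure$blocks[[j]])
    }
  }
  offsets <- .offset_template(arch)
  if (!is.null(arch$encoder_dim) && is.null(encoder)) {
    encoder <- with_seed(seed,
                         .random_encoder(arch$encoder_dim,
                                         arch$encoder_width))
  }
  structure(list(architecture = arch, weights = weights, offsets = offsets,
                 masks = masks, encoder = encoder, init_tag = "zero"),
            class = "model_state")
}

.offset_template <- function(arch) {
  if (arch$kind == "feed_forward") {
    K <- length(arch$layer_sizes) - 1L
    offs <- lapply(seq_len(K), function(k) numeric(arch$layer_sizes[k + 1L]))
    names(offs) <- paste0("b", seq_len(K))
  } else {
    offs <- c(list(b_state = numeric(arch$state_size)),
              stats::setNames(
                lapply(arch$post_layers, function(p) numeric(p$size)),
                paste0("b_post", seq_along(arch$post_layers))))
  }
  offs
}

#' @export
print.model_state <- function(x, ...) {
  n_active <- sum(vapply(seq_along(x$weights), function(i) {
    sum(x$masks[[i]] != 0)
  }, numeric(1)))
  n_total <- sum(vapply(x$weights, length, numeric(1)))
  cat(sprintf("<model_state> init '%s', %d/%d unmasked weight positions\n",
              x$init_tag, n_active, n_total))
  print(x$architecture)
  invisible(x)
}

#' Glorot uniform initialization limit
#'
#' Half-width `sqrt(6 / (fan_in + fan_out))` of the glorot-uniform range
#' for a connection block.
#' @param fan_in,fan_out Source and target layer sizes.
#' @return A positive real.
#' @export
glorot_limit <- function(fan_in, fan_out) sqrt(6 / (fan_in + fan_out))

.block_glorot_limits <- function(model) {
  vapply(model$weights, function(w) glorot_limit(nrow(w), ncol(w)),
         numeric(1))
}

.enforce_masks <- function(model) {
  for (i in seq_along(model$weights)) {
    model$weights[[i]] <- model$weights[[i]] * model$masks[[i]]
  }
  model
}

#' Initialization configurations
#'
#' @param method One of `"glorot"`, `"uniform"`, `"irnn"`, `"lightning"`,
#'   `"dense_diversity"`, `"sparse_diversity"`.
#' @param seed Integer seed.
#' @param uniform_range Half-width of the uniform init (default 0.05).
#' @param irnn_noise_sd Noise added to the identity recurrent block
#'   (default 0.001).
#' @param lightning_scale Magnitude of the connectivity seed weights in
#'   units of each block's glorot limit (default 2.5).
#' @return A list of class `init_config`.
#' @export
init_config <- function(method = c("glorot", "uniform", "irnn", "lightning",
                                   "dense_diversity", "sparse_diversity"),
                        seed = NULL, uniform_range = 0.05,
                        irnn_noise_sd = 0.001, lightning_scale = 2.5) {
  method <- match.arg(method)
  structure(list(method = method, seed = seed,
                 uniform_range = uniform_range,
                 irnn_noise_sd = irnn_noise_sd,
                 lightning_scale = lightning_scale),
            class = "init_config")
}

#' Randomly initialize a model
#'
#' Supported methods: `glorot` (per-block uniform with limit
#' `sqrt(6 / (fan_in + fan_out))`); `uniform` (U(-0.05, 0.05)); `irnn`
#' (identity recurrent state block plus N(0, 0.001) noise, glorot
#' elsewhere; recurrent architectures only); `lightning` (a documented
#' surrogate for the cited strategy of that name: glorot base plus one
#' large-magnitude seed weight per row and per column of every block, so
#' that sparsification at any mean degree >= 5 leaves the network almost
#' fully weakly connected); `dense_diversity` / `sparse_diversity`
#' (per-node in-degree drawn from [diversity_degree_sequence()]; that many
#' incoming positions get full-scale glorot weights, the rest near-zero
#' noise at 1/100 scale). Offsets always initialize to 0. Masked positions
#' are zeroed after initialization.
#'
#' @param model A [build_model()] state.
#' @param config An [init_config()] (or a method name string).
#' @param seed Overrides `config$seed` when given.
#' @return The initialized `model_state` (with `init_tag` set).
#' @export
init_random <- function(model, config = init_config(), seed = NULL) {
  if (is.character(config)) config <- init_config(config)
  if (!is.null(seed)) config$seed <- seed
  arch <- model$architecture
  lims <- .block_glorot_limits(model)
  with_seed(config$seed, {
    model$weights <- switch(
      config$method,
      glorot = lapply(seq_along(model$weights), function(i) {
        w <- model$weights[[i]]
        matrix(stats::runif(length(w), -lims[i], lims[i]), nrow(w), ncol(w))
      }),
      uniform = lapply(model$weights, function(w) {
        matrix(stats::runif(length(w), -config$uniform_range,
                            config$uniform_range), nrow(w), ncol(w))
      }),
      irnn = {
        if (arch$kind != "recurrent") {
          stop_config("irnn initialization needs a recurrent architecture")
        }
        lapply(seq_along(model$weights), function(i) {
          w <- model$weights[[i]]
          if (names(model$weights)[i] == "w_state") {
            diag(nrow(w)) +
              matrix(stats::rnorm(length(w), 0, config$irnn_noise_sd),
                     nrow(w), ncol(w))
          } else {
            matrix(stats::runif(length(w), -lims[i], lims[i]),
                   nrow(w), ncol(w))
          }
        })
      },
      lightning = lapply(seq_along(model$weights), function(i) {
        w <- model$weights[[i]]
        if (length(w) == 0L) return(w)
        w[] <- stats::runif(length(w), -lims[i], lims[i])
        big <- config$lightning_scale * lims[i]
        # one strong connection out of every source and into every target
        rows <- seq_len(nrow(w))
        w[cbind(rows, sample.int(ncol(w), nrow(w), replace = TRUE))] <-
          big * sample(c(-1, 1), nrow(w), replace = TRUE)
        cols <- seq_len(ncol(w))
        w[cbind(sample.int(nrow(w), ncol(w), replace = TRUE), cols)] <-
          big * sample(c(-1, 1), ncol(w), replace = TRUE)
        w
      }),
      dense_diversity = .init_diversity(model, "dense", lims),
      sparse_diversity = .init_diversity(model, "sparse", lims))
    names(model$weights) <- arch$blocks$name
    model$offsets <- .offset_template(arch)
    model$init_tag <- config$method
    .enforce_masks(model)
  })
}

.init_diversity <- function(model, kind, lims) {
  lapply(seq_along(model$weights), function(i) {
    w <- model$weights[[i]]
    if (length(w) == 0L) return(w)
    if (!model$architecture$blocks$structural[i]) {
      return(matrix(stats::runif(length(w), -lims[i], lims[i]),
                    nrow(w), ncol(w)))
    }
    # near-zero background, full-scale weights on d_in incoming positions
    w[] <- stats::runif(length(w), -lims[i] / 100, lims[i] / 100)
    d_in <- diversity_degree_sequence(kind, n = nrow(w) + 1L)[seq_len(ncol(w))]
    d_in <- pmin(d_in, nrow(w))
    for (j in seq_len(ncol(w))) {
      if (d_in[j] > 0) {
        rows <- sample.int(nrow(w), d_in[j])
        w[rows, j] <- stats::runif(d_in[j], -lims[i], lims[i])
      }
    }
    w
  })
}

#' Implant a ternary structure as initialization
#'
#' Structure implantation initializes a network from a wiring pattern
#' alone, with no weight values: entries with structure +1 are set to `+v`,
#' -1 to `-v`, 0 to 0, and uniform noise U(-v/10, +v/10) is then added to
#' *every* entry, so connections outside the implanted ("primary")
#' structure exist as small random "secondary" weights. `v` defaults to
#' each block's glorot limit. Masks are left untouched (all ones on a dense
#' model), so secondary weights stay trainable. Non-structural blocks
#' (dense readouts) are glorot-initialized.
#'
#' @param model A `model_state` whose structural blocks match `structure`.
#' @param structure A [ternary_structure()].
#' @param v Implantation magnitude: scalar or per-structural-block vector;
#'   `NULL` (default) uses the glorot limit of each block.
#' @param seed Integer seed for the noise.
#' @return The initialized `model_state`.
#' @export
implant_structure <- function(model, structure, v = NULL, seed = NULL) {
  arch <- model$architecture
  si <- which(arch$blocks$structural)
  if (length(structure$blocks) != length(si)) {
    stop_config("structure block count does not match the model")
  }
  lims <- .block_glorot_limits(model)
  if (is.null(v)) {
    v <- lims[si]
  } else {
    if (any(v <= 0)) stop_invalid("implantation magnitude v must be > 0")
    v <- rep_len(v, length(si))
  }
  with_seed(seed, {
    for (j in seq_along(si)) {
      i <- si[j]
      S <- structure$blocks[[j]]
      if (any(dim(S) != dim(model$weights[[i]]))) {
        stop_config("structure block ", j, " shape mismatch")
      }
      noise <- matrix(stats::runif(length(S), -v[j] / 10, v[j] / 10),
                      nrow(S), ncol(S))
      model$weights[[i]] <- v[j] * S + noise
    }
    for (i in setdiff(seq_along(model$weights), si)) {
      w <- model$weights[[i]]
      model$weights[[i]] <- matrix(stats::runif(length(w), -lims[i], lims[i]),
                                   nrow(w), ncol(w))
    }
    model$offsets <- .offset_template(arch)
    model$implant_v <- stats::setNames(v, arch$blocks$name[si])
    model$primary <- lapply(structure$blocks, function(S) S != 0)
    model$init_tag <- "structure_implantation"
    .enforce_masks(model)
  })
}

#' Implant a winning ticket (pretrained structure with its weights)
#'
#' Copies the `round(n * c)` globally strongest trained weights of
#' `trained_model` verbatim into their positions; every other position gets
#' small noise U(-v/10, v/10) with `v` the mean absolute copied weight.
#' Non-structural readout blocks are copied verbatim as a whole. Offsets
#' reset to 0.
#'
#' @param model Target `model_state` (same architecture).
#' @param trained_model Source `model_state` holding trained weights.
#' @param c Mean degree of the implanted ticket.
#' @param seed Integer seed for the background noise.
#' @return The initialized `model_state`.
#' @export
implant_winning_ticket <- function(model, trained_model, c, seed = NULL) {
  arch <- model$architecture
  if (!identical(arch$blocks, trained_model$architecture$blocks)) {
    stop_config("architectures do not match")
  }
  si <- which(arch$blocks$structural)
  src <- trained_model$weights[si]
  support <- sparsify_to_structure(src, c, n_nodes = arch$node_count)
  copied <- unlist(lapply(seq_along(si), function(j) {
    src[[j]][support$blocks[[j]] != 0]
  }))
  v <- mean(abs(copied))
  with_seed(seed, {
    for (j in seq_along(si)) {
      i <- si[j]
      keep <- support$blocks[[j]] != 0
      w <- matrix(stats::runif(length(keep), -v / 10, v / 10),
                  nrow(keep), ncol(keep))
      w[keep] <- src[[j]][keep]
      model$weights[[i]] <- w
    }
    for (i in setdiff(seq_along(model$weights), si)) {
      model$weights[[i]] <- trained_model$weights[[i]]
    }
    model$offsets <- .offset_template(arch)
    model$implant_v <- stats::setNames(rep(v, length(si)),
                                       arch$blocks$name[si])
    model$primary <- lapply(support$blocks, function(S) S != 0)
    model$init_tag <- "winning_ticket"
    .enforce_masks(model)
  })
}

#' Sparsify a model's structural blocks
#'
#' Convenience wrapper: runs [sparsify_to_structure()] on the model's
#' structural weight blocks with `n` = the architecture's node count.
#' @param model A `model_state`.
#' @param c Target mean degree.
#' @return A [ternary_structure()].
#' @export
model_structure <- function(model, c) {
  si <- which(model$architecture$blocks$structural)
  sparsify_to_structure(model$weights[si], c,
                        n_nodes = model$architecture$node_count)
}
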