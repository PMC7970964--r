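#' Solver configuration
#'
#' Plain SGD with momentum, categorical cross-entropy loss and accuracy
#' metric. Package defaults follow the published per-architecture solver
#' table: learning rate 0.05 / momentum 0 for feed-forward networks and
#' 0.03 / 0.01 for the large random recurrent networks; 30 epochs with
#' shuffled batches of 128 (feed-forward) or 256 (recurrent).
#'
#' @param learning_rate SGD step size.
#' @param momentum Momentum coefficient.
#' @param epochs Training epochs (default 30).
#' @param batch_size Batch size.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(learning_rate = 0.05, momentum = 0,
                          epochs = 30L, batch_size = 128L) {
  stopifnot(learning_rate >= 0, momentum >= 0, momentum < 1, epochs >= 1,
            batch_size >= 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size)),
            class = "solver_config")
}

#' @rdname solver_config
#' @param arch A `layered_architecture`; picks the published defaults for
#'   its kind (feed-forward: lr 0.05, momentum 0, batch 128; recurrent:
#'   lr 0.03, momentum 0.01, batch 256).
#' @export
default_solver <- function(arch) {
  if (arch$kind == "feed_forward") {
    solver_config(0.05, 0, 30L, 128L)
  } else {
    solver_config(0.03, 0.01, 30L, 256L)
  }
}

#' Perturbation configuration for disturbed/blocked training
#'
#' Gaussian noise `N(0, sigma)` is added to the targeted values (weights
#' XOR neuron offsets) before the optimization of every batch; the noise
#' accumulates in the values. In blocked mode the targeted values are
#' additionally excluded from gradient updates, and the untargeted values
#' are never disturbed.
#'
#' @param sigma Noise standard deviation, `>= 0`.
#' @param target `"weights"` or `"offsets"`.
#' @param blocked Logical: freeze the disturbed values.
#' @return A list of class `perturbation_config`.
#' @export
perturbation_config <- function(sigma, target = c("weights", "offsets"),
                                blocked = FALSE) {
  target <- match.arg(target)
  if (sigma < 0) stop_invalid("sigma must be >= 0")
  structure(list(sigma = sigma, target = target, blocked = blocked),
            class = "perturbation_config")
}

.act <- function(z, kind) {
  switch(kind,
         relu = pmax(z, 0),
         tanh = tanh(z),
         softmax = {
           e <- exp(z - apply(z, 1L, max))
           e / rowSums(e)
         })
}

.act_grad <- function(a, kind) {
  # derivative expressed through the activation value
  switch(kind,
         relu = (a > 0) * 1,
         tanh = 1 - a^2)
}

.encode_input <- function(model, x) {
  if (!is.null(model$encoder)) x %*% model$encoder else x
}

.add_offset <- function(z, b) sweep(z, 2L, b, "+")

.forward <- function(model, x) {
  arch <- model$architecture
  B <- nrow(x)
  if (arch$kind == "feed_forward") {
    E <- if (!is.null(arch$encoder_dim)) .encode_input(model, x) else NULL
    a <- if (!is.null(arch$encoder_dim)) {
      matrix(0, B, arch$layer_sizes[1L])
    } else x
    K <- length(arch$layer_sizes) - 1L
    acts <- vector("list", K + 1L)
    acts[[1L]] <- a
    for (k in seq_len(K)) {
      z <- .add_offset(a %*% model$weights[[k]], model$offsets[[k]])
      inj <- if (!is.null(arch$injections)) arch$injections[[k]] else NULL
      if (!is.null(inj)) {
        z[, inj[, "unit_column"]] <- z[, inj[, "unit_column"], drop = FALSE] +
          E[, inj[, "encoder_column"], drop = FALSE]
      }
      a <- .act(z, arch$activations[k])
      acts[[k + 1L]] <- a
    }
    list(probs = a, acts = acts, E = E)
  } else {
    inj <- .encode_input(model, x)
    Tn <- arch$recurrent_steps
    n <- arch$state_size
    s <- matrix(0, B, n)
    states <- vector("list", Tn + 1L)
    states[[1L]] <- s
    W <- model$weights[["w_state"]]
    b <- model$offsets[["b_state"]]
    for (t in seq_len(Tn)) {
      z <- .add_offset(s %*% W, b)
      z[, arch$input_index] <- z[, arch$input_index, drop = FALSE] + inj
      s <- tanh(z)
      states[[t + 1L]] <- s
    }
    P <- length(arch$post_layers)
    post_acts <- vector("list", P + 1L)
    post_acts[[1L]] <- s
    a <- s
    for (p in seq_len(P)) {
      z <- .add_offset(a %*% model$weights[[1L + p]],
                       model$offsets[[1L + p]])
      a <- .act(z, arch$post_layers[[p]]$activation)
      post_acts[[p + 1L]] <- a
    }
    list(probs = a, states = states, post_acts = post_acts, E = inj)
  }
}

.backward <- function(model, fwd, y_onehot) {
  arch <- model$architecture
  B <- nrow(y_onehot)
  gw <- lapply(model$weights, function(w) NULL)
  gb <- lapply(model$offsets, function(b) NULL)
  if (arch$kind == "feed_forward") {
    K <- length(arch$layer_sizes) - 1L
    dz <- (fwd$probs - y_onehot) / B
    for (k in rev(seq_len(K))) {
      gw[[k]] <- crossprod(fwd$acts[[k]], dz)
      gb[[k]] <- colSums(dz)
      if (k > 1L) {
        da <- dz %*% t(model$weights[[k]])
        dz <- da * .act_grad(fwd$acts[[k]], arch$activations[k - 1L])
      }
    }
  } else {
    P <- length(arch$post_layers)
    dz <- (fwd$probs - y_onehot) / B
    for (p in rev(seq_len(P))) {
      gw[[1L + p]] <- crossprod(fwd$post_acts[[p]], dz)
      gb[[1L + p]] <- colSums(dz)
      da <- dz %*% t(model$weights[[1L + p]])
      if (p > 1L) {
        dz <- da * .act_grad(fwd$post_acts[[p]],
                             arch$post_layers[[p - 1L]]$activation)
      } else {
        ds <- da
      }
    }
    W <- model$weights[["w_state"]]
    gW <- matrix(0, nrow(W), ncol(W))
    gbs <- numeric(arch$state_size)
    for (t in rev(seq_len(arch$recurrent_steps))) {
      dzt <- ds * (1 - fwd$states[[t + 1L]]^2)
      gW <- gW + crossprod(fwd$states[[t]], dzt)
      gbs <- gbs + colSums(dzt)
      ds <- dzt %*% t(W)
    }
    gw[["w_state"]] <- gW
    gb[["b_state"]] <- gbs
  }
  list(weights = gw, offsets = gb)
}

.one_hot <- function(y, n_classes) {
  m <- matrix(0, length(y), n_classes)
  m[cbind(seq_along(y), y + 1L)] <- 1
  m
}

#' Evaluate a model
#'
#' `predict_model` returns class probabilities; `model_accuracy` the
#' fraction of correct argmax predictions on a dataset split.
#' @param model A `model_state`.
#' @param x Input matrix (rows = samples).
#' @return `predict_model`: matrix of class probabilities.
#' @export
predict_model <- function(model, x) {
  .forward(model, x)$probs
}

#' @rdname predict_model
#' @param dataset A [labeled_dataset()].
#' @param split Split to evaluate (default `"validation"`).
#' @export
model_accuracy <- function(model, dataset, split = "validation") {
  d <- dataset_split(dataset, split)
  p <- predict_model(model, d$x)
  mean(max.col(p, ties.method = "first") - 1L == d$y)
}

.flatten_target <- function(model, target) {
  if (target == "weights") {
    unlist(model$weights, use.names = FALSE)
  } else {
    unlist(model$offsets, use.names = FALSE)
  }
}

#' Add Gaussian disturbance to a model's values
#'
#' Adds i.i.d. `N(0, sigma)` to every targeted value (all weight blocks,
#' or all neuron offsets). Used standalone and by [train_model()] before
#' the optimization of every batch.
#' @param model A `model_state`.
#' @param config A [perturbation_config()].
#' @param seed Integer seed.
#' @return The disturbed `model_state`.
#' @export
apply_disturbance <- function(model, config, seed = NULL) {
  if (config$sigma == 0) return(model)
  with_seed(seed, {
    if (config$target == "weights") {
      model$weights <- lapply(model$weights, function(w) {
        w + matrix(stats::rnorm(length(w), 0, config$sigma), nrow(w), ncol(w))
      })
    } else {
      model$offsets <- lapply(model$offsets, function(b) {
        b + stats::rnorm(length(b), 0, config$sigma)
      })
    }
    model
  })
}

#' Train a masked model with SGD
#'
#' Runs plain SGD with momentum on categorical cross entropy. Masks are
#' enforced after every optimizer step, so masked positions stay exactly 0
#' throughout. Recurrent models iterate their state for the configured
#' number of steps with the (encoded) input added to the pre-activation of
#' the input neurons at every step, starting from a zero state. Optional
#' per-epoch pruning hooks update the masks; optional disturbance noise is
#' added to the targeted values before the optimization of every batch
#' (see [perturbation_config()]). Validation accuracy is evaluated once
#' per epoch, after the pruning hook.
#'
#' @param model A `model_state` (already initialized).
#' @param dataset A [labeled_dataset()].
#' @param solver A [solver_config()]; default picked from the
#'   architecture.
#' @param prune `"none"`, `"iterative"`, or `"bio"`.
#' @param prune_c Target mean degree for pruning (required when pruning).
#' @param perturb Optional [perturbation_config()].
#' @param seed Integer seed controlling shuffling, pruning and noise.
#' @param record_structures Record the ternary structure (at `prune_c`, or
#'   `structure_c`) after every epoch.
#' @param structure_c Mean degree used for recorded structures.
#' @return A `training_record`: per-epoch `accuracy`, `best_accuracy`,
#'   `learn_curve_sum`, `initial_model`, `final_model`, optional
#'   `structures`, perturbation metrics `gamma` / `delta` (when disturbed),
#'   and `n_batches`.
#' @export
train_model <- function(model, dataset, solver = NULL,
                        prune = c("none", "iterative", "bio"),
                        prune_c = NULL, perturb = NULL, seed = NULL,
                        record_structures = FALSE, structure_c = NULL) {
  prune <- match.arg(prune)
  arch <- model$architecture
  if (is.null(solver)) solver <- default_solver(arch)
  if (prune != "none" && is.null(prune_c)) {
    stop_config("prune_c is required when pruning")
  }
  tr <- dataset_split(dataset, "train")
  n_classes <- arch$output_node_count
  initial_model <- model
  vel_w <- lapply(model$weights, function(w) w * 0)
  vel_b <- lapply(model$offsets, function(b) b * 0)
  acc <- numeric(solver$epochs)
  structures <- if (record_structures) vector("list", solver$epochs) else NULL
  sc <- if (!is.null(structure_c)) structure_c else prune_c
  n_batches <- 0L
  grad_sq_sum <- 0
  grad_n <- 0
  perturb_target0 <- if (!is.null(perturb)) {
    .flatten_target(model, perturb$target)
  } else NULL
  with_seed(seed, {
    for (epoch in seq_len(solver$epochs)) {
      idx <- sample.int(nrow(tr$x))
      starts <- seq(1L, length(idx), by = solver$batch_size)
      for (s0 in starts) {
        rows <- idx[s0:min(s0 + solver$batch_size - 1L, length(idx))]
        xb <- tr$x[rows, , drop = FALSE]
        yb <- .one_hot(tr$y[rows], n_classes)
        if (!is.null(perturb) && perturb$sigma > 0) {
          model <- apply_disturbance(model, perturb)
        }
        fwd <- .forward(model, xb)
        loss <- -mean(log(pmax(fwd$probs[yb == 1], 1e-12)))
        if (!is.finite(loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch)
        }
        grad <- .backward(model, fwd, yb)
        if (!is.null(perturb)) {
          g <- if (perturb$target == "weights") {
            gv <- unlist(grad$weights, use.names = FALSE)
            gv[unlist(model$masks, use.names = FALSE) != 0]
          } else {
            unlist(grad$offsets, use.names = FALSE)
          }
          grad_sq_sum <- grad_sq_sum + sum(g^2)
          grad_n <- grad_n + length(g)
        }
        block_weights <- !is.null(perturb) && perturb$blocked &&
          perturb$target == "weights"
        block_offsets <- !is.null(perturb) && perturb$blocked &&
          perturb$target == "offsets"
        if (!block_weights) {
          for (i in seq_along(model$weights)) {
            vel_w[[i]] <- solver$momentum * vel_w[[i]] -
              solver$learning_rate * grad$weights[[i]]
            model$weights[[i]] <- (model$weights[[i]] + vel_w[[i]]) *
              model$masks[[i]]
          }
        } else {
          model <- .enforce_masks(model)
        }
        if (!block_offsets) {
          for (i in seq_along(model$offsets)) {
            vel_b[[i]] <- solver$momentum * vel_b[[i]] -
              solver$learning_rate * grad$offsets[[i]]
            model$offsets[[i]] <- model$offsets[[i]] + vel_b[[i]]
          }
        }
        n_batches <- n_batches + 1L
      }
      if (prune == "iterative") {
        model <- iterative_prune_step(model, prune_c)
      } else if (prune == "bio") {
        model <- bio_prune_step(model, prune_c)
      }
      if (record_structures && !is.null(sc)) {
        structures[[epoch]] <- model_structure(model, sc)
      }
      acc[epoch] <- model_accuracy(model, dataset, "validation")
    }
  })
  gamma <- delta <- NA_real_
  if (!is.null(perturb) && perturb$sigma > 0) {
    gamma <- sqrt(grad_sq_sum / grad_n) / perturb$sigma
    target1 <- .flatten_target(model, perturb$target)
    dchi <- target1 - perturb_target0
    if (perturb$target == "weights") {
      # masked positions are not trainable values: exclude them
      dchi <- dchi[unlist(model$masks, use.names = FALSE) != 0]
    }
    delta <- sqrt(mean(dchi^2)) / (sqrt(n_batches) * perturb$sigma)
  }
  structure(list(accuracy = acc,
                 best_accuracy = max(acc),
                 learn_curve_sum = sum(acc),
                 initial_model = initial_model,
                 final_model = model,
                 structures = structures,
                 gamma = gamma, delta = delta,
                 n_batches = n_batches,
                 solver = solver, prune = prune, prune_c = prune_c,
                 perturb = perturb, seed = seed),
            class = "training_record")
}

#' @export
print.training_record <- function(x, ...) {
  cat(sprintf("<training_record> %d epochs: best accuracy %.3f, learn-curve sum %.2f\n",
              length(x$accuracy), x$best_accuracy, x$learn_curve_sum))
  invisible(x)
}

#' Export a training record's learning curve as CSV
#' @param record A `training_record`.
#' @param path Output CSV path.
#' @return `path` invisibly.
#' @export
write_learning_curve <- function(record, path) {
  utils::write.csv(data.frame(epoch = seq_along(record$accuracy),
                              validation_accuracy = record$accuracy),
                   path, row.names = FALSE)
  invisible(path)
}

#' Iterative (magnitude) pruning step
#'
#' Re-selects the `round(n * c)` globally strongest weights of the
#' structural blocks as the active mask; all other structural positions
#' are zeroed and frozen until the next update.
#' @param model A `model_state`.
#' @param c Target mean degree.
#' @return The pruned `model_state`.
#' @export
iterative_prune_step <- function(model, c) {
  si <- which(model$architecture$blocks$structural)
  struct <- sparsify_to_structure(model$weights[si], c,
                                  n_nodes = model$architecture$node_count)
  for (j in seq_along(si)) {
    model$masks[[si[j]]] <- abs(struct$blocks[[j]])
  }
  .enforce_masks(model)
}

#' Stochastic ("bio") pruning step
#'
#' Biological turnover of connections: after each epoch the step may build
#' up at most `Pois(rate)` new connections (uniformly among currently
#' masked positions, re-initialized with small uniform noise), delete at
#' most `Pois(rate)` weak connections, and never breaks a strong one.
#' Strong connections are the `round(n * c)` largest-magnitude active
#' weights; weak connections are all other active ones (deleted weakest
#' first). The realized mean degree may therefore drift around `c`.
#'
#' @param model A `model_state`.
#' @param c Average connectivity defining the protected strong set.
#' @param rate Poisson rate for creations and deletions (default 20).
#' @param seed Integer seed.
#' @return The updated `model_state`.
#' @export
bio_prune_step <- function(model, c, rate = 20, seed = NULL) {
  if (rate < 0) stop_invalid("rate must be >= 0")
  if (rate == 0) return(model)
  si <- which(model$architecture$blocks$structural)
  lens <- vapply(model$weights[si], length, numeric(1))
  offs <- c(0, cumsum(lens))
  w <- unlist(lapply(model$weights[si], as.numeric), use.names = FALSE)
  m <- unlist(lapply(model$masks[si], as.numeric), use.names = FALSE)
  lims <- .block_glorot_limits(model)[si]
  v <- if (!is.null(model$implant_v)) unname(model$implant_v) else lims
  with_seed(seed, {
    k <- round(model$architecture$node_count * c)
    active <- which(m != 0)
    strong <- active[order_by_magnitude(w[active])[seq_len(min(k, length(active)))]]
    weak <- setdiff(active, strong)
    n_new <- stats::rpois(1L, rate)
    n_del <- stats::rpois(1L, rate)
    inactive <- which(m == 0)
    if (n_new > 0 && length(inactive)) {
      grow <- inactive[sample.int(length(inactive),
                                  min(n_new, length(inactive)))]
      m[grow] <- 1
      blk <- findInterval(grow - 1L, offs[-length(offs)])
      w[grow] <- stats::runif(length(grow), -v[blk] / 10, v[blk] / 10)
    }
    if (n_del > 0 && length(weak)) {
      # delete the weakest first
      doomed <- weak[order(abs(w[weak]))][seq_len(min(n_del, length(weak)))]
      m[doomed] <- 0
      w[doomed] <- 0
    }
    for (j in seq_along(si)) {
      if (lens[j] == 0) next
      rng <- (offs[j] + 1L):offs[j + 1L]
      dm <- dim(model$weights[[si[j]]])
      model$weights[[si[j]]] <- matrix(w[rng], dm[1L], dm[2L])
      model$masks[[si[j]]] <- matrix(m[rng], dm[1L], dm[2L])
    }
    .enforce_masks(model)
  })
}

#' Relative gradient and change RMS metrics
#'
#' The two disturbance metrics: `gamma` is the RMS of the per-value loss
#' gradients divided by the noise level `sigma` (the strength of the
#' gradient relative to the added disturbance); `delta` is the RMS of the
#' total value change from the initial state divided by `sqrt(N) * sigma`,
#' the expected RMS displacement of a pure `N`-step noise random walk —
#' so an untrained run accumulating only noise has `delta` near 1.
#'
#' @param gradient_history Numeric vector/matrix of per-value gradient
#'   samples (all batches concatenated).
#' @param value_history List with `initial` and `final` numeric vectors of
#'   the targeted values.
#' @param sigma Noise standard deviation, `> 0`.
#' @param N Number of batches.
#' @return List with `gamma` and `delta`.
#' @export
perturbation_metrics <- function(gradient_history, value_history, sigma, N) {
  if (sigma <= 0) stop_invalid("sigma must be > 0: metrics undefined")
  if (N < 1) stop_invalid("N must be >= 1")
  g <- as.numeric(gradient_history)
  gamma <- sqrt(mean(g^2)) / sigma
  dchi <- as.numeric(value_history$final) - as.numeric(value_history$initial)
  delta <- sqrt(mean(dchi^2)) / (sqrt(N) * sigma)
  list(gamma = gamma, delta = delta)
}

#' Factorial sweep over disturbance settings
#'
#' Trains the base model once per cell of
#' `sigma_grid x targets x blocked_modes x seeds` and collects the best
#' accuracy, the `gamma` / `delta` metrics and the Spearman rank
#' correlation between trained and initial weights.
#'
#' @param base_model An initialized (typically pruned) `model_state`.
#' @param dataset A [labeled_dataset()].
#' @param sigma_grid Numeric vector of noise levels.
#' @param targets Subset of `c("weights", "offsets")`.
#' @param blocked_modes Subset of `c(FALSE, TRUE)`.
#' @param seeds Integer vector of seeds (one training run per seed).
#' @param solver Optional [solver_config()].
#' @return List with `results` (one row per run) and `summary` (mean and
#'   standard deviation per cell).
#' @export
run_perturbation_sweep <- function(base_model, dataset, sigma_grid,
                                   targets = c("weights", "offsets"),
                                   blocked_modes = c(FALSE, TRUE),
                                   seeds = 1:10, solver = NULL) {
  cells <- expand.grid(sigma = sigma_grid, target = targets,
                       blocked = blocked_modes, seed = seeds,
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    cell <- cells[r, ]
    pert <- if (cell$sigma > 0 || cell$blocked) {
      perturbation_config(cell$sigma, cell$target, cell$blocked)
    } else NULL
    rec <- train_model(base_model, dataset, solver = solver,
                       perturb = pert, seed = cell$seed)
    sp <- spearman_weight_similarity(rec$final_model, rec$initial_model,
                                     edge_scope = "union_active")
    data.frame(cell, best_accuracy = rec$best_accuracy,
               gamma = rec$gamma, delta = rec$delta,
               spearman_to_init = sp)
  })
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(
    cbind(best_accuracy, spearman_to_init) ~ sigma + target + blocked,
    data = results,
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  list(results = results, summary = summary)
}
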