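#' Pairwise run-comparison ("toast") matrices
#'
#' Compares many training runs at once on a square grid whose rows and
#' columns are run subvariants (typically `init` / `trained` states on two
#' datasets, four subvariants per run). One plot is built out of two
#' triangles carrying different measures:
#' type 1 pairs a structural measure (fraction of odd edges between the
#' runs' ternary structures, upper-right) with the Spearman R of the edge
#' weights (lower-left); type 2 pairs the degree-sequence isomorphism
#' possibility score (upper-right) with the Spearman R of the neuron
#' offsets (lower-left). Self-comparisons are flagged identical.
#'
#' @param runs Named list of runs; each run is a named list of
#'   `model_state` subvariants (identical names across runs, e.g.
#'   `init_A`, `trained_A`, `init_B`, `trained_B`).
#' @param plot_type 1 (edges/weights) or 2 (isomorphism/offsets).
#' @param c Mean degree at which structures are extracted for the
#'   structural measures.
#' @param iso_threshold Isomorphism possibility cutoff used for the
#'   significance marks (default 0.9).
#' @param significance_fn Optional callable `(measure_value, cell_kind)`
#'   returning a logical mark; `cell_kind` is `"upper"` or `"lower"`. The
#'   default marks upper cells of type 2 at `score >= iso_threshold` and
#'   leaves other cells unmarked.
#' @return A `toast_matrix`: `upper`, `lower` (numeric matrices),
#'   `identical` (logical), `significant` (logical), `labels`,
#'   `plot_type`.
#' @export
build_toast_matrices <- function(runs, plot_type = 1, c = NULL,
                                 iso_threshold = 0.9,
                                 significance_fn = NULL) {
  stopifnot(length(runs) >= 2L, plot_type %in% c(1, 2))
  sub_names <- names(runs[[1L]])
  if (length(sub_names) < 1L || is.null(sub_names)) {
    stop_config("each run must be a named list of subvariants")
  }
  for (r in runs) {
    if (!identical(names(r), sub_names)) {
      stop_config("all runs must share the same subvariant names")
    }
  }
  if (is.null(c)) {
    stop_config("the mean degree c of the compared structures is required")
  }
  labels <- as.vector(t(outer(names(runs), sub_names, paste, sep = ":")))
  models <- unlist(runs, recursive = FALSE)
  n <- length(models)
  upper <- lower <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  ident <- diag(n) == 1
  structs <- graphs <- NULL
  if (plot_type == 1) {
    structs <- lapply(models, model_structure, c = c)
  } else {
    graphs <- lapply(models, function(m) {
      structure_to_graph(model_structure(m, c))
    })
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (plot_type == 1) {
        upper[i, j] <- odd_edge_count(structs[[i]], structs[[j]])$fraction
        lower[i, j] <- spearman_weight_similarity(models[[i]], models[[j]],
                                                  edge_scope = "union_active")
      } else {
        upper[i, j] <- isomorphism_possibility(graphs[[i]], graphs[[j]],
                                               threshold = iso_threshold)$score
        lower[i, j] <- spearman_offset_similarity(models[[i]], models[[j]])
      }
    }
  }
  if (is.null(significance_fn)) {
    significance_fn <- function(value, cell_kind) {
      if (plot_type == 2 && cell_kind == "upper") {
        !is.na(value) && value >= iso_threshold
      } else FALSE
    }
  }
  signif_mat <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      kind <- if (j > i) "upper" else "lower"
      val <- if (j > i) upper[i, j] else lower[i, j]
      signif_mat[i, j] <- isTRUE(significance_fn(val, kind))
    }
  }
  structure(list(upper = upper, lower = lower, identical = ident,
                 significant = signif_mat, labels = labels,
                 plot_type = plot_type, c = c),
            class = "toast_matrix")
}

#' @export
print.toast_matrix <- function(x, ...) {
  cat(sprintf("<toast_matrix> type %d, %d subvariants\n", x$plot_type,
              length(x$labels)))
  invisible(x)
}

#' Export a toast matrix as CSV
#'
#' Writes the combined matrix (upper-right triangle = structural measure,
#' lower-left = rank correlation, diagonal NA) to `path`.
#' @param toast A `toast_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_toast_csv <- function(toast, path) {
  combined <- toast$lower
  ut <- upper.tri(combined)
  combined[ut] <- toast$upper[ut]
  utils::write.csv(combined, path, row.names = TRUE)
  invisible(path)
}

#' Plot a toast matrix
#'
#' Renders the two-triangle layout with `graphics::image()`: the
#' upper-right triangle shows the structural measure, the lower-left the
#' rank-correlation measure; diagonal (identical) cells are marked.
#' @param x A `toast_matrix`.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.toast_matrix <- function(x, ...) {
  n <- length(x$labels)
  combined <- x$lower
  ut <- upper.tri(combined)
  combined[ut] <- x$upper[ut]
  graphics::image(seq_len(n), seq_len(n), t(combined[n:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  graphics::axis(1, at = seq_len(n), labels = x$labels, las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(n), labels = rev(x$labels), las = 2,
                 cex.axis = 0.6)
  for (i in seq_len(n)) {
    graphics::points(i, n + 1L - i, pch = 4, col = "red")
  }
  invisible(x)
}
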