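#' Spearman rank similarity of model weights
#'
#' Spearman rank correlation between two models' weights over a chosen set
#' of edge positions, structural blocks concatenated. Scopes: `"all"` (every
#' position), `"union_active"` (positions active — unmasked and nonzero —
#' in either model; the default, matching how trained sparse runs are
#' compared), `"primary_only"` (positions in both models' primary support:
#' the implanted structure for implanted models, the active set
#' otherwise). Ties get average ranks.
#'
#' @param modelA,modelB `model_state` objects with identical architectures.
#' @param edge_scope `"all"`, `"union_active"`, or `"primary_only"`.
#' @return Spearman R in [-1, 1].
#' @export
spearman_weight_similarity <- function(modelA, modelB,
                                       edge_scope = c("union_active", "all",
                                                      "primary_only")) {
  edge_scope <- match.arg(edge_scope)
  if (!identical(modelA$architecture$blocks, modelB$architecture$blocks)) {
    stop_config("models have different architectures")
  }
  si <- which(modelA$architecture$blocks$structural)
  wa <- unlist(lapply(modelA$weights[si], as.numeric), use.names = FALSE)
  wb <- unlist(lapply(modelB$weights[si], as.numeric), use.names = FALSE)
  primary_of <- function(model, w) {
    if (!is.null(model$primary)) {
      unlist(lapply(model$primary, as.vector), use.names = FALSE)
    } else w != 0
  }
  keep <- switch(edge_scope,
                 all = rep(TRUE, length(wa)),
                 union_active = wa != 0 | wb != 0,
                 primary_only = primary_of(modelA, wa) &
                   primary_of(modelB, wb))
  if (sum(keep) < 3L) {
    stop_degenerate("fewer than 3 positions in scope; correlation undefined")
  }
  stats::cor(wa[keep], wb[keep], method = "spearman")
}

#' Spearman rank similarity of neuron offsets
#'
#' As [spearman_weight_similarity()] but over the concatenated neuron
#' offset vectors; used in the second toast-plot type to show how much the
#' training process moved the offsets.
#' @inheritParams spearman_weight_similarity
#' @return Spearman R in [-1, 1].
#' @export
spearman_offset_similarity <- function(modelA, modelB) {
  ba <- unlist(modelA$offsets, use.names = FALSE)
  bb <- unlist(modelB$offsets, use.names = FALSE)
  if (length(ba) != length(bb) || length(ba) < 3L) {
    stop_degenerate("offset vectors unusable for correlation")
  }
  if (stats::sd(ba) == 0 || stats::sd(bb) == 0) {
    if (identical(ba, bb)) return(1)
    return(NA_real_)  # constant offsets (e.g. untrained): undefined
  }
  stats::cor(ba, bb, method = "spearman")
}

#' Degree-sequence isomorphism possibility score
#'
#' Two isomorphic graphs necessarily have identical degree sequences, so
#' comparing the sorted per-node (in-degree, out-degree) pairs gives a
#' cheap necessary-condition screen: the score is the fraction of matching
#' positions after sorting both sequences. A score of 1 means the graphs
#' *could* be isomorphic (no false negatives); anything below 1 certifies
#' they are not. The conventional significance mark declares "possibly
#' isomorphic" at score >= 0.9.
#'
#' @param graphA,graphB [directed_signed_graph()] objects.
#' @return List with `score` in [0, 1], `possible` (score >= threshold),
#'   and `node_count_mismatch`.
#' @param threshold Possibility cutoff (default 0.9).
#' @export
isomorphism_possibility <- function(graphA, graphB, threshold = 0.9) {
  if (graphA$node_count != graphB$node_count) {
    return(list(score = 0, possible = FALSE, node_count_mismatch = TRUE))
  }
  seq_of <- function(g) {
    din <- tabulate(g$edges$to, nbins = g$node_count)
    dout <- tabulate(g$edges$from, nbins = g$node_count)
    ord <- order(din, dout)
    cbind(din[ord], dout[ord])
  }
  a <- seq_of(graphA)
  b <- seq_of(graphB)
  score <- mean(a[, 1] == b[, 1] & a[, 2] == b[, 2])
  list(score = score, possible = score >= threshold,
       node_count_mismatch = FALSE)
}

#' Number of possible edges of an architecture
#'
#' Sums source-count times target-count over all structural connection
#' blocks; a recurrent state block contributes `n^2` (self-loops
#' included).
#' @param arch A `layered_architecture`.
#' @return Integer-valued count.
#' @export
possible_edges <- function(arch) {
  stopifnot(inherits(arch, "layered_architecture"))
  b <- arch$blocks
  sum(b$nrow[b$structural] * b$ncol[b$structural])
}

log10_factorial <- function(n) lgamma(n + 1) / log(10)

#' Number of unique labeled graphs, log10 scale
#'
#' Computes `log10` of the count of unique graph forms via log-gamma,
#' never forming the factorials. Two published conventions are supported:
#' `"M_over_m"` computes `log10(M! / m!)`; `"falling"` computes
#' `log10(M! / (M - m)!)` (the falling factorial, i.e. ordered choices of
#' `m` out of `M` possible edges). The two readings coincide only at
#' `m = M / 2`-symmetric cases, and published per-architecture values mix
#' them, so the convention is an explicit argument.
#'
#' @param M Number of possible edges.
#' @param m Number of existing edges, `0 <= m <= M`.
#' @param convention `"M_over_m"` (default) or `"falling"`.
#' @return `log10` of the count (a nonnegative real).
#' @export
unique_graphs_log10 <- function(M, m, convention = c("M_over_m", "falling")) {
  convention <- match.arg(convention)
  if (m < 0 || m > M) stop_invalid("m must lie in [0, M]")
  if (convention == "M_over_m") {
    log10_factorial(M) - log10_factorial(m)
  } else {
    log10_factorial(M) - log10_factorial(M - m)
  }
}

#' Number of isomorphic graph variants, log10 scale
#'
#' Free nodes — nodes not pinned to an input or output role — can be
#' permuted within their layer without changing the computation, giving
#' `prod(f_l!)` isomorphic variants. Returned as `log10` via log-gamma.
#' With all `f_l` in \{0, 1\} there is a single variant (`log10 = 0`).
#'
#' @param free_node_counts Integer vector of per-layer free-node counts
#'   (see [free_node_counts()]).
#' @return `log10` of the isomorphism count.
#' @export
isomorphism_count_log10 <- function(free_node_counts) {
  if (any(free_node_counts < 0)) stop_invalid("free-node counts must be >= 0")
  sum(log10_factorial(free_node_counts))
}

#' Graph count report for an architecture
#'
#' Bundles the combinatorial reference quantities: possible edges `M`,
#' existing edges `m` (default `round(node_count * c)`), the log10 unique
#' graph count, and the log10 isomorphism count from the architecture's
#' free nodes.
#' @param arch A `layered_architecture`.
#' @param c Mean degree used for `m` (ignored when `m` given).
#' @param m Explicit existing-edge count.
#' @param convention Passed to [unique_graphs_log10()].
#' @return A list of class `graph_count_report`.
#' @export
graph_count_report <- function(arch, c = NULL, m = NULL,
                               convention = "M_over_m") {
  M <- possible_edges(arch)
  if (is.null(m)) {
    if (is.null(c)) stop_config("either c or m is required")
    m <- round(arch$node_count * c)
  }
  f <- free_node_counts(arch)
  structure(list(possible_edges = M, existing_edges = m,
                 log10_unique_graphs = unique_graphs_log10(M, m, convention),
                 log10_isomorphisms = isomorphism_count_log10(f),
                 free_node_counts = f),
            class = "graph_count_report")
}

#' @export
print.graph_count_report <- function(x, ...) {
  fmt <- function(lg) {
    sprintf("%.2f x 10^%d", 10^(lg - floor(lg)), as.integer(floor(lg)))
  }
  cat(sprintf("<graph_count_report> M = %d, m = %d\n", x$possible_edges,
              x$existing_edges))
  cat("  unique graphs:", fmt(x$log10_unique_graphs), "\n")
  if (all(x$free_node_counts <= 1)) {
    cat("  isomorphisms: none (no free nodes)\n")
  } else {
    cat("  isomorphisms:", fmt(x$log10_isomorphisms), "\n")
  }
  invisible(x)
}

#' Best accuracy and learn-curve sum of a training record
#'
#' The two learning statistics used for run comparisons: the maximum and
#' the sum of the per-epoch validation accuracies (the sum is a
#' learning-speed measure: fast learners accumulate accuracy early).
#' @param record A `training_record`.
#' @return List with `best_accuracy` and `learn_curve_sum`.
#' @export
learn_curve_statistics <- function(record) {
  if (!length(record$accuracy)) stop_invalid("empty accuracy sequence")
  list(best_accuracy = max(record$accuracy),
       learn_curve_sum = sum(record$accuracy))
}

#' One-sided two-sample t-test
#'
#' Tests "group A is better than group B" (alternative: mean(A) >
#' mean(B)). Pooled-variance by default; Welch available. A negative t
#' indicates B was better; its one-sided p is then > 0.5.
#'
#' @param groupA,groupB Numeric vectors (>= 2 values each).
#' @param var_equal Pooled variance (default `TRUE`).
#' @return A list of class `stat_test_result`: `t`, `p` (one-sided),
#'   `n_A`, `n_B`.
#' @export
one_sided_t_test <- function(groupA, groupB, var_equal = TRUE) {
  if (length(groupA) < 2L || length(groupB) < 2L) {
    stop_invalid("each group needs >= 2 values")
  }
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0) {
    if (mean(groupA) == mean(groupB)) {
      stop_degenerate("zero variance in both groups: test undefined")
    }
  }
  ht <- stats::t.test(groupA, groupB, alternative = "greater",
                      var.equal = var_equal)
  structure(list(t = unname(ht$statistic), p = ht$p.value,
                 n_A = length(groupA), n_B = length(groupB),
                 var_equal = var_equal),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("<stat_test_result> t = %.3f, one-sided p = %.4g (n = %d + %d)\n",
              x$t, x$p, x$n_A, x$n_B))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param m_tests Number of data accesses / tests, >= 1.
#' @return `alpha / m_tests`.
#' @export
bonferroni_threshold <- function(alpha, m_tests) {
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must lie in (0, 1)")
  if (m_tests < 1) stop_invalid("m_tests must be >= 1")
  alpha / m_tests
}
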