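# Independent oracles used across the suite. All are deliberately naive:
# brute-force sorting, transitive closure, exhaustive permutation search,
# cumulative log sums -- never the code paths they check.

# brute-force global top-k selection over a list of matrices: returns a
# logical list marking the k largest-|w| positions (ties by flat order)
oracle_top_k <- function(blocks, k) {
  flat <- unlist(lapply(blocks, as.numeric))
  ord <- order(-abs(flat), seq_along(flat))
  keep <- logical(length(flat))
  keep[ord[seq_len(k)]] <- TRUE
  offset <- 0L
  lapply(blocks, function(b) {
    m <- matrix(keep[offset + seq_along(b)], nrow(b), ncol(b))
    offset <<- offset + length(b)
    m
  })
}

# largest weakly connected component fraction by boolean transitive closure
oracle_wcc_fraction <- function(n, edges) {
  reach <- diag(n) == 1
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      reach[edges$from[r], edges$to[r]] <- TRUE
      reach[edges$to[r], edges$from[r]] <- TRUE
    }
  }
  for (k in seq_len(n)) {
    reach <- reach | (reach[, k] %o% reach[k, ])
  }
  comp_sizes <- rowSums(reach)
  max(comp_sizes) / n
}

# exhaustive directed-graph isomorphism test for n <= 6
oracle_isomorphic <- function(adjA, adjB) {
  n <- nrow(adjA)
  if (n != nrow(adjB) || sum(adjA) != sum(adjB)) return(FALSE)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  for (p in perms(seq_len(n))) {
    if (all(adjA[p, p] == adjB)) return(TRUE)
  }
  FALSE
}

# log10(n!) by cumulative summation, independent of lgamma
oracle_log10_factorial <- function(n) {
  if (n <= 1) return(0)
  sum(log10(seq_len(n)))
}

# one-sided permutation test p-value for mean(A) > mean(B)
oracle_permutation_p <- function(a, b, n_perm = 10000L) {
  obs <- mean(a) - mean(b)
  pool <- c(a, b)
  na <- length(a)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pool), na)
    if (mean(pool[idx]) - mean(pool[-idx]) >= obs) hits <- hits + 1L
  }
  hits / n_perm
}

# small deterministic graph fixtures
fixture_two_cliques <- function() {
  e <- rbind(expand.grid(from = 1:3, to = 1:3),
             expand.grid(from = 4:10, to = 4:10))
  e <- e[e$from != e$to, ]
  e$sign <- 1
  directed_signed_graph(10, e)
}

fixture_ring <- function(n = 8) {
  directed_signed_graph(n, data.frame(from = seq_len(n),
                                      to = c(seq_len(n)[-1], 1L),
                                      sign = 1))
}

tiny_connectome <- function(seed = 11) {
  cn <- generate_synthetic_connectome(neuron_count = 40, sensory_count = 15,
                                      muscle_count = 12, synapse_edges = 180,
                                      muscle_edges = 60, seed = seed)
  assign_connection_signs(cn, seed = seed + 1)
}

tiny_dataset <- function(n_per_class = 30, noise_sd = 0.15, seed = 7,
                         dim = 784) {
  generate_classification_dataset(n_per_class, noise_sd = noise_sd,
                                  seed = seed, dim = dim)
}
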