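test_that("weight similarity hits its exact anchors and null bound", {
  a <- arch_feed_forward(c(80, 60, 10))
  m <- init_random(build_model(a), "glorot", seed = 1)
  expect_equal(spearman_weight_similarity(m, m, "all"), 1.0)

  rev_m <- m
  rev_m$weights <- lapply(m$weights, function(w) -w)
  expect_equal(spearman_weight_similarity(m, rev_m, "all"), -1.0)

  m2 <- init_random(build_model(a), "glorot", seed = 2)
  expect_lt(abs(spearman_weight_similarity(m, m2, "all")), 0.05)

  tiny <- init_random(build_model(arch_feed_forward(c(1, 1, 2))), "glorot",
                      seed = 3)
  tiny$weights <- lapply(tiny$weights, function(w) w * 0)
  expect_error(spearman_weight_similarity(tiny, tiny, "union_active"),
               class = "structnet_degenerate_input")

  b <- arch_feed_forward(c(80, 50, 10))
  expect_error(
    spearman_weight_similarity(m, init_random(build_model(b), "glorot",
                                              seed = 1)),
    class = "structnet_config_error")
})

test_that("degree-sequence screening never misses a true isomorphism", {
  g <- generate_gnp(12, 3, seed = 4)
  # node-relabeled copy: identical degree multiset
  perm <- sample(12)
  relabeled <- directed_signed_graph(12, data.frame(
    from = perm[g$edges$from], to = perm[g$edges$to], sign = g$edges$sign))
  expect_equal(isomorphism_possibility(g, relabeled)$score, 1.0)

  # different edge counts can never score 1
  g2 <- generate_gnp(12, 5, seed = 5)
  expect_lt(isomorphism_possibility(g, g2)$score, 1)
  expect_equal(isomorphism_possibility(g, generate_gnp(9, 3, seed = 1))$score,
               0)

  # brute-force oracle on small graphs: score 1 whenever an exhaustive
  # permutation search finds an isomorphism (zero false negatives)
  found_iso <- 0L
  for (s in 1:40) {
    set.seed(s)
    n <- sample(3:6, 1)
    ga <- generate_gnp(n, runif(1, 0.5, n / 2), seed = s)
    adjA <- (graph_to_adjacency(ga) != 0) * 1
    if (s %% 2 == 0) {
      p <- sample(n)
      adjB <- adjA[p, p]
    } else {
      gb <- generate_gnp(n, runif(1, 0.5, n / 2), seed = 1000 + s)
      adjB <- (graph_to_adjacency(gb) != 0) * 1
    }
    gb <- graph_from_adjacency(adjB)
    score <- isomorphism_possibility(ga, gb)$score
    if (oracle_isomorphic(adjA, adjB)) {
      found_iso <- found_iso + 1L
      expect_equal(score, 1.0)
    }
  }
  expect_gt(found_iso, 10L)  # the corpus actually contained isomorphic pairs
})

test_that("possible-edge counts follow the block sums", {
  expect_equal(possible_edges(arch_lenet_300_100()), 266200)
  expect_equal(possible_edges(arch_recurrent_gnp(1194)), 1194^2)
  expect_equal(possible_edges(arch_feed_forward(c(1, 1))), 1)
  # additive over blocks and invariant to which layer the sizes sit in
  expect_equal(possible_edges(arch_feed_forward(c(5, 7, 3))),
               5 * 7 + 7 * 3)
})

test_that("log-scale graph counts match exact arithmetic", {
  expect_equal(unique_graphs_log10(100, 100), 0)
  expect_equal(unique_graphs_log10(10, 3), log10(factorial(10) / factorial(3)))
  expect_equal(10^unique_graphs_log10(10, 3), 604800)
  expect_error(unique_graphs_log10(5, 6), class = "structnet_invalid_parameter")

  # log-gamma route vs cumulative-log oracle for all arguments <= 500
  for (n in c(0:20, 50, 171, 300, 500)) {
    expect_equal(structnet:::log10_factorial(n), oracle_log10_factorial(n),
                 tolerance = 1e-12)
  }
  for (m in c(0, 1, 17, 250, 500)) {
    expect_equal(unique_graphs_log10(500, m),
                 oracle_log10_factorial(500) - oracle_log10_factorial(m),
                 tolerance = 1e-10)
    expect_equal(unique_graphs_log10(500, m, convention = "falling"),
                 oracle_log10_factorial(500) - oracle_log10_factorial(500 - m),
                 tolerance = 1e-10)
  }

  expect_equal(isomorphism_count_log10(c(5, 3)), log10(120 * 6))
  expect_equal(isomorphism_count_log10(0), 0)
  expect_equal(isomorphism_count_log10(c(1, 1, 0)), 0)
  expect_error(isomorphism_count_log10(-1),
               class = "structnet_invalid_parameter")
})

test_that("free-node conventions reproduce the architecture table", {
  expect_equal(free_node_counts(arch_lenet_300_100()), c(300L, 100L))
  expect_equal(free_node_counts(arch_lenet_4x300()), rep(300L, 4))
  expect_equal(free_node_counts(arch_recurrent_gnp(1194, 784)), 400L)
  expect_equal(free_node_counts(arch_recurrent_encoded(177)), 0L)
})

test_that("learn-curve statistics recompute from the stored sequence", {
  rec <- structure(list(accuracy = rep(0.9, 30)), class = "training_record")
  st <- learn_curve_statistics(rec)
  expect_equal(st$best_accuracy, 0.9)
  expect_equal(st$learn_curve_sum, 27.0)

  one <- structure(list(accuracy = 0.42), class = "training_record")
  expect_equal(learn_curve_statistics(one)$best_accuracy,
               learn_curve_statistics(one)$learn_curve_sum)

  set.seed(6)
  curve <- runif(30)
  rec2 <- structure(list(accuracy = curve), class = "training_record")
  expect_equal(learn_curve_statistics(rec2)$learn_curve_sum, sum(curve))
})

test_that("one-sided t-test matches its anchors and a permutation oracle", {
  x <- c(1, 2, 3, 4, 5)
  r <- one_sided_t_test(x, x)
  expect_equal(r$t, 0)
  expect_equal(r$p, 0.5)

  r2 <- one_sided_t_test(x + 100, x)
  expect_lt(r2$p, 1e-10)

  expect_error(one_sided_t_test(rep(1, 5), rep(1, 5)),
               class = "structnet_degenerate_input")
  expect_error(one_sided_t_test(1, c(1, 2)),
               class = "structnet_invalid_parameter")

  # permutation oracle on 10 random 10-vs-10 normal pairs
  set.seed(7)
  for (i in 1:10) {
    a <- rnorm(10, mean = runif(1, 0, 1))
    b <- rnorm(10)
    p_t <- one_sided_t_test(a, b)$p
    p_perm <- oracle_permutation_p(a, b, n_perm = 10000L)
    expect_lt(abs(p_t - p_perm), 0.02)
  }
})

test_that("Bonferroni threshold is exact", {
  th <- bonferroni_threshold(0.05, 88)
  expect_equal(th * 88, 0.05)
  expect_equal(round(100 * th, 3), 0.057)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(1.2, 4),
               class = "structnet_invalid_parameter")
})
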