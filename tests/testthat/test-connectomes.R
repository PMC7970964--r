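test_that("synthetic connectome hits requested counts and round-trips", {
  cn <- generate_synthetic_connectome(seed = 1)
  expect_equal(cn$neuron_count, 369L)
  expect_equal(cn$muscle_count, 134L)
  expect_equal(nrow(cn$neuron_edges), 3888L)
  expect_equal(nrow(cn$muscle_edges), 1018L)
  expect_equal(sum(cn$sensory_flags), 136L)
  expect_true(all(cn$neuron_edges$weight >= 1))
  expect_false(any(cn$neuron_edges$from == cn$neuron_edges$to))

  cn2 <- generate_synthetic_connectome(seed = 1)
  expect_identical(cn$neuron_edges, cn2$neuron_edges)

  nd <- withr::local_tempfile(fileext = ".csv")
  md <- withr::local_tempfile(fileext = ".csv")
  small <- generate_synthetic_connectome(30, 10, 8, 60, 20, seed = 2)
  write_celegans_connectome(small, nd, md)
  back <- load_celegans_connectome(nd, md)
  expect_equal(back$neuron_count, 30L)
  expect_equal(back$muscle_count, 8L)
  key <- function(e) sort(paste(e$from, e$to, e$weight))
  expect_equal(key(back$neuron_edges), key(small$neuron_edges))
  expect_equal(key(back$muscle_edges), key(small$muscle_edges))

  expect_error(generate_synthetic_connectome(5, 2, 2, 100, 2),
               class = "structnet_invalid_parameter")
})

test_that("an all-zero adjacency loads as a valid empty connectome", {
  nd <- withr::local_tempfile(fileext = ".csv")
  md <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(matrix(0, 6, 6), nd, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(matrix(0, 6, 3), md, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  cn <- load_celegans_connectome(nd, md)
  expect_equal(nrow(cn$neuron_edges), 0L)
  expect_equal(nrow(cn$muscle_edges), 0L)
  expect_warning(assign_connection_signs(cn, seed = 1), "empty")
})

test_that("sign assignment is neuron-homogeneous with a uniform fraction", {
  cn <- generate_synthetic_connectome(100, 30, 20, 600, 150, seed = 3)

  # collapsed range: exact count of inhibitory neurons
  s <- assign_connection_signs(cn, c(0.25, 0.25), seed = 4)
  expect_equal(sum(s$signs == -1), round(0.25 * 100))

  # every neuron's out-edges share one sign, across both edge blocks
  all_edges <- rbind(s$neuron_edges[c("from", "sign")],
                     s$muscle_edges[c("from", "sign")])
  per_neuron <- split(all_edges$sign, all_edges$from)
  expect_true(all(vapply(per_neuron, function(x) length(unique(x)) == 1L,
                         logical(1))))

  # drawn fractions are uniform on [0.2, 0.3] (KS at 1%)
  fr <- vapply(1:50, function(sd) {
    assign_connection_signs(cn, seed = sd)$inhibitory_fraction
  }, numeric(1))
  expect_gt(stats::ks.test(fr, "punif", 0.2, 0.3)$p.value, 0.01)
})

test_that("human-connectome preprocessing thresholds, directs and signs edges", {
  M <- generate_synthetic_human_matrix(177, seed = 5)
  g <- preprocess_human_connectome(M, target_mean_degree = 22.4, seed = 6)
  # round(177 * 22.4) / 2 = 1982 directed edges, one per undirected link
  expect_equal(nrow(g$edges), 1982L)
  expect_false(anyDuplicated(g$edges[c("from", "to")]) > 0)
  # no reciprocal pairs: each link got exactly one direction
  fwd <- paste(g$edges$from, g$edges$to)
  rev <- paste(g$edges$to, g$edges$from)
  expect_length(intersect(fwd, rev), 0L)

  gf <- preprocess_human_connectome(M, 22.4, seed = 6,
                                    edge_convention = "full")
  expect_equal(nrow(gf$edges), 3965L)

  # sign balance over seeds: binomial 99% CI around 0.5
  exc <- vapply(1:20, function(s) {
    mean(preprocess_human_connectome(M, 22.4, seed = s)$edges$sign == 1)
  }, numeric(1))
  expect_lt(abs(mean(exc) - 0.5), 2.58 * sqrt(0.25 / (1982 * 20)))

  expect_error(preprocess_human_connectome(matrix(1:9, 3, 3)),
               class = "structnet_format_error")
})

test_that("threshold on a deterministic matrix keeps the largest entries", {
  M <- matrix(0, 10, 10)
  M[upper.tri(M)] <- seq_len(45)
  M <- M + t(M)
  g <- preprocess_human_connectome(M, target_mean_degree = 2, seed = 1)
  # round(10 * 2) / 2 = 10 strongest undirected links = values 36..45
  undirected <- unique(t(apply(g$edges[c("from", "to")], 1, sort)))
  vals <- M[undirected]
  expect_setequal(vals, 36:45)
})

test_that("recurrent connectome spec exposes the exact maskable positions", {
  cn <- generate_synthetic_connectome(seed = 7)
  cn <- assign_connection_signs(cn, seed = 8)
  b <- celegans_recurrent_spec(cn, seed = 9)
  expect_equal(possible_edges(b$architecture), 369L^2 + 369L * 134L)
  expect_equal(possible_edges(b$architecture), 185607L)

  # mask nonzero pattern equals the connectome edge set
  nz <- which(b$structure$blocks[[1]] != 0, arr.ind = TRUE)
  expect_setequal(paste(nz[, 1], nz[, 2]),
                  paste(cn$neuron_edges$from, cn$neuron_edges$to))
  nzm <- which(b$structure$blocks[[2]] != 0, arr.ind = TRUE)
  expect_setequal(paste(nzm[, 1], nzm[, 2]),
                  paste(cn$muscle_edges$from, cn$muscle_edges$to))
})

test_that("an edgeless connectome still yields a defined forward pass", {
  cn <- connectome_graph(20, 8, data.frame(from = integer(), to = integer(),
                                           weight = numeric()),
                         data.frame(from = integer(), to = integer(),
                                    weight = numeric()),
                         sensory_flags = c(rep(TRUE, 10), rep(FALSE, 10)))
  b <- suppressWarnings(celegans_recurrent_spec(cn, seed = 1, input_dim = 16,
                                                n_classes = 4))
  m <- init_random(build_model(b), "glorot", seed = 2)
  p <- predict_model(m, matrix(runif(3 * 16), 3, 16))
  expect_equal(dim(p), c(3L, 4L))
  expect_equal(rowSums(p), rep(1, 3))
})

test_that("feed-forward flattening follows directed distance to the muscles", {
  # chain a -> b -> c -> muscle: layers deepen with falling distance
  cn <- connectome_graph(3, 1,
                         data.frame(from = c(1, 2), to = c(2, 3), weight = 1),
                         data.frame(from = 3, to = 1, weight = 1),
                         sensory_flags = c(TRUE, FALSE, FALSE))
  cn <- assign_connection_signs(cn, c(0, 0), seed = 1)
  expect_equal(distance_to_output(cn), c(3, 2, 1))
  b <- celegans_lenet_spec(cn, seed = 2, input_dim = 4, n_classes = 2)
  expect_equal(attr(b, "layer_assignment"), c(1L, 2L, 3L))
  expect_equal(attr(b, "dropped_nodes"), 0L)

  # distances agree with a Floyd-Warshall oracle on random connectomes
  for (s in 1:5) {
    cns <- generate_synthetic_connectome(12, 4, 4, 25, 8, seed = s)
    n <- 12
    D <- matrix(Inf, n + 4, n + 4)
    diag(D) <- 0
    D[cbind(cns$neuron_edges$from, cns$neuron_edges$to)] <- 1
    D[cbind(cns$muscle_edges$from, n + cns$muscle_edges$to)] <- 1
    for (k in seq_len(n + 4)) {
      D <- pmin(D, outer(D[, k], D[k, ], "+"))
    }
    oracle_d <- apply(D[seq_len(n), n + seq_len(4), drop = FALSE], 1, min)
    expect_equal(distance_to_output(cns), oracle_d)
  }
})

test_that("layer binning never puts a feeder shallower than its target on a DAG", {
  cn <- tiny_connectome()
  b <- celegans_lenet_spec(cn, seed = 3, input_dim = 16)
  lay <- attr(b, "layer_assignment")
  d <- distance_to_output(cn)
  e <- cn$neuron_edges
  ok <- is.finite(d[e$from]) & is.finite(d[e$to])
  # distance can drop by at most 1 along an edge, so a target is never
  # binned more than one layer deeper than its source
  expect_true(all(lay[e$to[ok]] <= lay[e$from[ok]] + 1L))
})

test_that("G(n,p) reference keeps the muscle block and randomizes neurons", {
  cn <- generate_synthetic_connectome(80, 25, 20, 500, 140, seed = 10)
  cn <- assign_connection_signs(cn, seed = 11)
  b0 <- celegans_recurrent_spec(cn, seed = 12, input_dim = 32)
  counts <- vapply(1:10, function(s) {
    br <- celegans_gnp_reference_spec(cn, seed = s, input_dim = 32)
    # muscle block identical edge-for-edge
    expect_identical(br$structure$blocks[[2]] != 0,
                     b0$structure$blocks[[2]] != 0)
    sum(br$structure$blocks[[1]] != 0)
  }, numeric(1))
  p <- 500 / (80 * 79)
  se <- sqrt(80 * 79 * p * (1 - p) / 10)
  expect_lt(abs(mean(counts) - 500), 3 * se)
  # degree sequence of the neuron block essentially never matches the source
  same <- vapply(1:10, function(s) {
    br <- celegans_gnp_reference_spec(cn, seed = s, input_dim = 32)
    ga <- structure_to_graph(ternary_structure(list(br$structure$blocks[[1]]),
                                               1, 80))
    gb <- structure_to_graph(ternary_structure(list(b0$structure$blocks[[1]]),
                                               1, 80))
    isomorphism_possibility(ga, gb)$score == 1
  }, logical(1))
  expect_false(any(same))
})

test_that("spec bundles build forward-pass-compatible models", {
  cn <- tiny_connectome()
  ds <- tiny_dataset(n_per_class = 3, dim = 784)
  for (bundle in list(celegans_recurrent_spec(cn, seed = 1),
                      celegans_lenet_spec(cn, seed = 1),
                      celegans_gnp_reference_spec(cn, seed = 1))) {
    m <- init_random(build_model(bundle), "glorot", seed = 2)
    p <- predict_model(m, dataset_split(ds, "train")$x[1:5, , drop = FALSE])
    expect_equal(dim(p), c(5L, 10L))
    expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  }

  M <- generate_synthetic_human_matrix(60, seed = 3)
  hb <- human_connectome_spec(preprocess_human_connectome(M, 10, seed = 4),
                              seed = 5)
  m <- init_random(build_model(hb), "uniform", seed = 6)
  p <- predict_model(m, dataset_split(ds, "train")$x[1:4, , drop = FALSE])
  expect_equal(dim(p), c(4L, 10L))

  dir <- withr::local_tempdir()
  save_spec_bundle(hb, dir)
  expect_true(file.exists(file.path(dir, "architecture.json")))
  expect_true(file.exists(file.path(dir, "structure_1.csv")))
})
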