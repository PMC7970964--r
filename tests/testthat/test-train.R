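# shared fixtures: a small separable task and a pruned recurrent model
local_task <- function(dim = 120, n_per_class = 60, noise_sd = 0.15,
                       seed = 2) {
  generate_classification_dataset(n_per_class, noise_sd = noise_sd,
                                  seed = seed, dim = dim)
}

local_recurrent_model <- function(n = 160, input = 120, c = 22,
                                  init = "uniform", seed = 4) {
  g <- generate_gnp(n, c, seed = 3)
  st <- ternary_structure(list(sign(graph_to_adjacency(g))),
                          mean_degree(g), n)
  b <- connectome_spec_bundle(arch_recurrent(n, input_index = seq_len(input)),
                              st)
  init_random(build_model(b), init, seed = seed)
}

test_that("zero learning rate leaves the model untouched and the curve flat", {
  ds <- local_task(dim = 40, n_per_class = 12)
  m <- init_random(build_model(arch_feed_forward(c(40, 20, 10))), "glorot",
                   seed = 1)
  rec <- train_model(m, ds, solver_config(0, 0, epochs = 3, batch_size = 32),
                     seed = 1)
  expect_identical(rec$final_model$weights, m$weights)
  expect_identical(rec$final_model$offsets, m$offsets)
  expect_length(unique(rec$accuracy), 1L)
})

test_that("a glorot LeNet solves the easy synthetic task within five epochs", {
  ds <- local_task(dim = 784, n_per_class = 72, noise_sd = 0.1, seed = 1)
  # nearest-prototype oracle confirms the task is essentially separable
  expect_gt(prototype_accuracy(ds), 0.98)
  m <- init_random(build_model(arch_lenet_300_100()), "glorot", seed = 1)
  rec <- train_model(m, ds, solver_config(0.05, 0, epochs = 5,
                                          batch_size = 128), seed = 1)
  expect_gt(rec$best_accuracy, 0.9)
  expect_equal(rec$best_accuracy, max(rec$accuracy))
  expect_equal(rec$learn_curve_sum, sum(rec$accuracy))
})

test_that("a sparse random recurrent network learns above chance quickly", {
  ds <- local_task()
  m <- local_recurrent_model()
  rec <- train_model(m, ds, solver_config(0.05, 0.01, epochs = 5,
                                          batch_size = 64), seed = 1)
  expect_gt(rec$best_accuracy, 0.5)
})

test_that("training runs are reproducible bit for bit", {
  ds <- local_task(dim = 40, n_per_class = 12)
  m <- init_random(build_model(arch_feed_forward(c(40, 16, 10))), "glorot",
                   seed = 2)
  r1 <- train_model(m, ds, solver_config(0.05, 0.01, epochs = 2,
                                         batch_size = 32), seed = 9)
  r2 <- train_model(m, ds, solver_config(0.05, 0.01, epochs = 2,
                                         batch_size = 32), seed = 9)
  expect_identical(r1$final_model$weights, r2$final_model$weights)
  expect_identical(r1$accuracy, r2$accuracy)
})

test_that("masks stay enforced through training and pruning", {
  ds <- local_task()
  m <- local_recurrent_model()
  mask0 <- m$masks$w_state
  rec <- train_model(m, ds, solver_config(0.05, 0.01, epochs = 3,
                                          batch_size = 64), seed = 5)
  expect_true(all(rec$final_model$weights$w_state[mask0 == 0] == 0))
  expect_identical(rec$final_model$masks$w_state, mask0)

  # iterative pruning: active count is exact and re-selection idempotent
  mp <- init_random(build_model(arch_feed_forward(c(50, 30, 10))), "glorot",
                    seed = 6)
  n_nodes <- 90
  p1 <- iterative_prune_step(mp, 4)
  active <- sum(vapply(p1$masks, function(x) sum(x != 0), numeric(1)))
  expect_equal(active, round(n_nodes * 4))
  expect_true(all(unlist(p1$weights)[unlist(p1$masks) == 0] == 0))
  p2 <- iterative_prune_step(p1, 4)
  expect_identical(p2$masks, p1$masks)
  # surviving set equals the brute-force top-|w| selection
  keep <- oracle_top_k(mp$weights, round(n_nodes * 4))
  expect_equal(lapply(p1$masks, function(x) x != 0), keep)
})

test_that("pruned training keeps exactly the strongest weights each epoch", {
  ds <- local_task(dim = 40, n_per_class = 12)
  m <- init_random(build_model(arch_feed_forward(c(40, 20, 10))), "glorot",
                   seed = 7)
  rec <- train_model(m, ds, solver_config(0.05, 0, epochs = 3,
                                          batch_size = 32),
                     prune = "iterative", prune_c = 3, seed = 7,
                     record_structures = TRUE)
  final <- rec$final_model
  expect_equal(sum(unlist(final$masks) != 0), round(70 * 3))
  expect_true(all(unlist(final$weights)[unlist(final$masks) == 0] == 0))
  expect_length(rec$structures, 3L)
  expect_equal(structure_edge_count(rec$structures[[3]]), round(70 * 3))
})

test_that("bio pruning protects the strong set and drifts within Poisson bounds", {
  m <- init_random(build_model(arch_feed_forward(c(30, 25, 10))), "glorot",
                   seed = 8)
  n_nodes <- 65
  m <- iterative_prune_step(m, 9)   # 585 active, strong set will be 195
  strong_k <- round(n_nodes * 3)
  w <- unlist(m$weights)
  strong_idx <- order(-abs(w), seq_along(w))[seq_len(strong_k)]

  m1 <- bio_prune_step(m, 3, rate = 20, seed = 1)
  w1 <- unlist(m1$weights)
  expect_true(all(w1[strong_idx] == w[strong_idx]))   # never broken

  expect_identical(bio_prune_step(m, 3, rate = 0), m)

  # creations and deletions are balanced Poisson draws: the active count
  # drift over many steps stays within 3 sd of the Skellam difference
  steps <- 120
  cur <- m
  for (s in seq_len(steps)) cur <- bio_prune_step(cur, 3, rate = 20, seed = s)
  drift <- sum(unlist(cur$masks) != 0) - sum(unlist(m$masks) != 0)
  expect_lt(abs(drift), 3 * sqrt(2 * 20 * steps))
})

test_that("disturbance targets exactly the configured values", {
  m <- init_random(build_model(arch_feed_forward(c(30, 20, 10))), "glorot",
                   seed = 9)
  expect_identical(apply_disturbance(m, perturbation_config(0, "weights")), m)

  d <- apply_disturbance(m, perturbation_config(0.02, "weights"), seed = 10)
  expect_identical(d$offsets, m$offsets)
  diffs <- unlist(d$weights) - unlist(m$weights)
  n <- length(diffs)
  expect_lt(abs(var(diffs) - 0.02^2), 3 * sqrt(2 / n) * 0.02^2)

  o <- apply_disturbance(m, perturbation_config(0.02, "offsets"), seed = 11)
  expect_identical(o$weights, m$weights)
  expect_false(identical(o$offsets, m$offsets))
})

test_that("gamma and delta follow their closed-form limits", {
  # all gradient components equal sigma -> gamma = 1; zero gradients -> 0
  pm <- perturbation_metrics(rep(0.05, 100),
                             list(initial = rep(0, 10), final = rep(0, 10)),
                             sigma = 0.05, N = 4)
  expect_equal(pm$gamma, 1)
  expect_equal(perturbation_metrics(rep(0, 50),
                                    list(initial = 1:5, final = 1:5),
                                    0.1, 2)$gamma, 0)
  expect_error(perturbation_metrics(1, list(initial = 1, final = 1), 0, 1),
               class = "structnet_invalid_parameter")

  # untrained run: values accumulate pure noise, so delta is close to 1
  ds <- local_task()
  m <- local_recurrent_model()
  rec <- train_model(m, ds, solver_config(0, 0, epochs = 3, batch_size = 64),
                     perturb = perturbation_config(0.01, "weights"),
                     seed = 12)
  expect_lt(abs(rec$delta - 1), 0.05)
})

test_that("blocked values are frozen while the rest keeps training", {
  ds <- local_task()
  m <- local_recurrent_model()
  # blocked weights, no noise: weights must be bitwise unchanged
  rb <- train_model(m, ds, solver_config(0.05, 0.01, epochs = 2,
                                         batch_size = 64),
                    perturb = perturbation_config(0, "weights",
                                                  blocked = TRUE),
                    seed = 13)
  expect_identical(rb$final_model$weights, m$weights)
  expect_false(identical(rb$final_model$offsets, m$offsets))

  # blocked + disturbed offsets: weights still learn, accuracy improves
  ro <- train_model(m, ds, solver_config(0.05, 0.01, epochs = 3,
                                         batch_size = 64),
                    perturb = perturbation_config(0.005, "offsets",
                                                  blocked = TRUE),
                    seed = 13)
  expect_gt(ro$best_accuracy, ro$accuracy[1] + 0.05)
  expect_gt(ro$best_accuracy, 0.5)
})

test_that("the disturbance sweep covers its factorial grid", {
  ds <- local_task(dim = 40, n_per_class = 12)
  g <- generate_gnp(36, 10, seed = 3)
  st <- ternary_structure(list(sign(graph_to_adjacency(g))),
                          mean_degree(g), 36)
  b <- connectome_spec_bundle(arch_recurrent(36, input_index = 1:36,
                                             recurrent_steps = 10L), st)
  m <- init_random(build_model(b), "uniform", seed = 4)
  # recurrent arch reads 36-dim input directly; regenerate matching data
  ds36 <- generate_classification_dataset(12, noise_sd = 0.15, seed = 2,
                                          dim = 36)
  sweep <- run_perturbation_sweep(m, ds36, sigma_grid = c(0, 0.01),
                                  targets = "weights",
                                  blocked_modes = FALSE, seeds = 1:2,
                                  solver = solver_config(0.05, 0.01,
                                                         epochs = 2,
                                                         batch_size = 32))
  expect_equal(nrow(sweep$results), 4L)
  # the sigma = 0 cell reproduces the undisturbed baseline exactly
  baseline <- train_model(m, ds36,
                          solver_config(0.05, 0.01, epochs = 2,
                                        batch_size = 32), seed = 1)
  base <- subset(sweep$results, sigma == 0 & seed == 1)
  expect_identical(base$best_accuracy, baseline$best_accuracy)
  expect_true(all(c("best_accuracy", "gamma", "delta", "spearman_to_init")
                  %in% names(sweep$results)))
})
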