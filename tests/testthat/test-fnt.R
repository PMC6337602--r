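test_that("tree evaluation matches the closed-form Gaussian activation", {
  node <- fnt_function_node(list(fnt_leaf(1), fnt_leaf(2)),
                            weights = c(1, 1), m = 1, n_act = 1)
  expect_equal(eval_tree(node, matrix(c(0.5, 0.5), nrow = 1)), 1)
  node2 <- fnt_function_node(list(fnt_leaf(1), fnt_leaf(2)),
                             weights = c(1, 0), m = 0, n_act = 1)
  expect_equal(eval_tree(node2, matrix(c(1, 42), nrow = 1)), exp(-1))
})

test_that("tree evaluation equals an independent recursive evaluator", {
  set.seed(13)
  cfg <- train_config(max_depth = 4L)
  trees <- init_population(train_config(population_size = 50L,
                                        max_depth = 4L), 6L, seed = 21)
  for (tree in trees) {
    X <- matrix(rnorm(5 * 6), nrow = 5)
    got <- eval_tree(tree, X)
    want <- apply(X, 1, function(x) oracle_eval(tree, x))
    expect_equal(got, want)
    expect_true(all(got > 0 & got <= 1))
  }
})

test_that("evaluation errors on dimension problems and non-finite input", {
  node <- fnt_function_node(list(fnt_leaf(1), fnt_leaf(5)),
                            weights = c(1, 1), m = 0, n_act = 1)
  expect_error(eval_tree(node, matrix(0, 1, 2)), "feature 5")
  expect_error(eval_tree(node, matrix(c(NA, 1, 1, 1, 1), 1)), "non-finite")
  model <- structure(list(root = node, feature_dim = 5L, threshold = 0.5),
                     class = "fnt_model")
  expect_error(eval_tree(model, matrix(0, 2, 3)), "mismatch")
})

test_that("random populations respect size, depth, arity and determinism", {
  cfg <- train_config(population_size = 10L, max_depth = 3L,
                      function_arities = c(2L, 3L))
  pop <- init_population(cfg, 7L, seed = 3)
  expect_length(pop, 10L)
  expect_identical(pop, init_population(cfg, 7L, seed = 3))
  expect_false(identical(pop, init_population(cfg, 7L, seed = 4)))

  big <- init_population(train_config(population_size = 500L,
                                      max_depth = 3L), 7L, seed = 9)
  for (tree in big) {
    expect_true(tree_depth(tree) <= 3L)
    expect_true(acetree:::is_function_node(tree))
    expect_true(acetree:::validate_tree(tree, 7L, 3L))
  }
  expect_error(init_population(cfg, 0L), "feature_dim")
})

test_that("structure evolution keeps invariants and preserves the elite", {
  set.seed(31)
  X <- matrix(rnorm(40 * 5), 40)
  y <- rep(c(0, 1), 20)
  cfg <- train_config(population_size = 15L, max_depth = 3L)
  fit_fn <- function(tree) sqrt(mean((eval_tree(tree, X) - y)^2))
  pop <- init_population(cfg, 5L, seed = 1)
  best_before <- min(vapply(pop, fit_fn, numeric(1)))
  for (g in 1:15) {
    step <- evolve_structure(pop, fit_fn, cfg, 5L, seed = 100 + g)
    pop <- step$population
    for (tree in pop) {
      expect_true(tree_depth(tree) <= cfg$max_depth)
      expect_true(acetree:::validate_tree(tree, 5L, cfg$max_depth))
    }
    # elitism: best fitness never worsens across generations
    best_now <- min(vapply(pop, fit_fn, numeric(1)))
    expect_lte(best_now, best_before + 1e-12)
    best_before <- best_now
  }
})

test_that("degenerate operators reduce to cloning/mutation", {
  set.seed(17)
  cfg <- train_config(population_size = 2L, crossover_rate = 0,
                      mutation_rate = 0)
  pop <- init_population(cfg, 3L, seed = 5)
  X <- matrix(rnorm(20 * 3), 20)
  y <- rep(c(0, 1), 10)
  fit_fn <- function(tree) sqrt(mean((eval_tree(tree, X) - y)^2))
  nxt <- evolve_structure(pop, fit_fn, cfg, 3L, seed = 6)$population
  # with no crossover and no mutation every survivor is a copy of an input
  for (tree in nxt) {
    expect_true(any(vapply(pop, identical, logical(1), y = tree)))
  }
})

test_that("PSO never worsens fitness and is deterministic", {
  set.seed(23)
  X <- matrix(rnorm(60), ncol = 1)
  y <- as.integer(X[, 1] > 0)
  tree <- fnt_function_node(list(fnt_leaf(1), fnt_leaf(1)),
                            weights = c(0.5, 0.5), m = 0.2, n_act = 0.8)
  cfg <- train_config(swarm_size = 12L, swarm_iterations = 15L)
  before <- sqrt(mean((eval_tree(tree, X) - y)^2))
  out1 <- optimize_parameters(tree, X, y, cfg, seed = 8)
  expect_lte(out1$fitness, before + 1e-12)
  out2 <- optimize_parameters(tree, X, y, cfg, seed = 8)
  expect_identical(out1, out2)
  expect_error(optimize_parameters(tree, X, rep(1, 60), cfg, seed = 8),
               "both classes")
})

test_that("PSO separates a linearly separable 1-D problem", {
  set.seed(29)
  x <- c(rnorm(40, -2, 0.3), rnorm(40, 2, 0.3))
  y <- rep(c(0L, 1L), each = 40)
  X <- matrix(x, ncol = 1)
  tree <- fnt_function_node(list(fnt_leaf(1), fnt_leaf(1)),
                            weights = c(0.5, 0.5), m = 0, n_act = 1)
  out <- optimize_parameters(tree, X, y, train_config(swarm_size = 20L,
                                                      swarm_iterations = 40L),
                             seed = 10)
  acc <- mean((eval_tree(out$tree, X) >= 0.5) == (y == 1))
  expect_gte(acc, 0.95)
})

test_that("training separates clusters, is deterministic, round-trips JSON", {
  set.seed(37)
  X <- rbind(matrix(rnorm(50 * 3, 5, 0.5), 50),
             matrix(rnorm(50 * 3, -5, 0.5), 50))
  y <- rep(c(1L, 0L), each = 50)
  cfg <- fast_config()
  m1 <- train_fnt(X, y, cfg, seed = 2)
  acc <- mean(predict(m1, X)$label == y)
  expect_gte(acc, 0.95)

  m2 <- train_fnt(X, y, cfg, seed = 2)
  j1 <- fnt_to_json(m1)
  expect_identical(j1, fnt_to_json(m2))

  back <- fnt_from_json(j1)
  expect_equal(back$root, m1$root)
  expect_equal(eval_tree(back, X), eval_tree(m1, X))

  path <- tempfile(fileext = ".json")
  fnt_to_json(m1, path)
  expect_equal(fnt_from_json(path)$root, m1$root)

  expect_error(train_fnt(X, rep(1, 100), cfg), "both classes")
})

test_that("training on shuffled labels yields chance-level AUC", {
  ds <- generate_dataset(synthetic_spec(n = 6, n_pos = 250, n_neg = 250,
                                        effect_size = 2, seed = 41))
  tab <- default_property_table()
  iv <- influence_vector(influence_spec("quadratic", a2 = 1, b2 = 0), 6)
  X <- encode_windows(ds, tab, iv, reduce = "sum")
  y <- with_seed_shuffle(dataset_labels(ds), 43)
  he <- holdout_eval(X, y, fast_config(), seed = 44)
  expect_gte(he$report$auc, 0.35)
  expect_lte(he$report$auc, 0.65)
})

test_that("prediction is stateless, batch-consistent, and thresholded", {
  set.seed(47)
  cfg <- fast_config()
  X <- matrix(rnorm(30 * 4), 30)
  y <- as.integer(X[, 1] + X[, 2] > 0)
  m <- train_fnt(X, y, cfg, seed = 3)
  batch <- predict(m, X)
  single <- do.call(rbind, lapply(seq_len(nrow(X)), function(i)
    predict(m, X[i, ])))
  expect_equal(batch$score, single$score)
  perm <- sample(nrow(X))
  expect_equal(predict(m, X[perm, ])$score, batch$score[perm])
  # boundary convention: score exactly at threshold is positive
  m$threshold <- batch$score[1]
  expect_equal(predict(m, X)$label[1], 1L)
})
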