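#' Training configuration for the flexible neural tree
#'
#' Structure search is genetic programming (tournament selection, subtree
#' crossover, subtree/point mutation, elitism); parameter search is particle
#' swarm optimization (PSO) over all edge weights and activation `(m, n_act)`
#' pairs of the incumbent best tree. The two alternate each generation.
#'
#' @param function_arities Allowed arities of function nodes.
#' @param population_size Number of trees in the GP population.
#' @param generations Number of alternating GP/PSO generations.
#' @param tournament_size Tournament size for parent selection.
#' @param crossover_rate Probability an offspring is produced by subtree
#'   crossover (otherwise cloned from its parent).
#' @param mutation_rate Probability an offspring is mutated.
#' @param swarm_size Number of PSO particles.
#' @param swarm_iterations PSO iterations per generation.
#' @param fitness `"rmse"` (root mean squared error of the score against the
#'   0/1 label; default) or `"one_minus_auc"` for imbalanced data. Both are
#'   minimized.
#' @param max_depth Maximum tree depth (root = 1).
#' @param seed Default master seed used by [train_fnt()] when none is given.
#' @return An object of class `train_config`.
#' @export
train_config <- function(function_arities = c(2L, 3L),
                         population_size = 20L,
                         generations = 8L,
                         tournament_size = 3L,
                         crossover_rate = 0.5,
                         mutation_rate = 0.4,
                         swarm_size = 15L,
                         swarm_iterations = 20L,
                         fitness = c("rmse", "one_minus_auc"),
                         max_depth = 3L,
                         seed = 1L) {
  fitness <- match.arg(fitness)
  cfg <- list(function_arities = as.integer(function_arities),
              population_size = as.integer(population_size),
              generations = as.integer(generations),
              tournament_size = as.integer(tournament_size),
              crossover_rate = crossover_rate,
              mutation_rate = mutation_rate,
              swarm_size = as.integer(swarm_size),
              swarm_iterations = as.integer(swarm_iterations),
              fitness = fitness,
              max_depth = as.integer(max_depth),
              seed = as.integer(seed))
  stopifnot(all(cfg$function_arities >= 2L),
            cfg$population_size >= 2L, cfg$generations >= 1L,
            cfg$tournament_size >= 1L,
            cfg$crossover_rate >= 0, cfg$crossover_rate <= 1,
            cfg$mutation_rate >= 0, cfg$mutation_rate <= 1,
            cfg$swarm_size >= 2L, cfg$swarm_iterations >= 0L,
            cfg$max_depth >= 2L)
  structure(cfg, class = "train_config")
}

# --- random tree construction -----------------------------------------------

# Grow a random subtree with at most `budget` levels; `allow_leaf = FALSE`
# forces a function node at the top (used for roots).
random_subtree <- function(feature_dim, config, budget, allow_leaf = TRUE) {
  if (budget <= 1L || (allow_leaf && runif(1) < 0.5)) {
    return(fnt_leaf(sample.int(feature_dim, 1L)))
  }
  arity <- config$function_arities[sample.int(length(config$function_arities), 1L)]
  children <- lapply(seq_len(arity), function(i)
    random_subtree(feature_dim, config, budget - 1L, allow_leaf = TRUE))
  fnt_function_node(children,
                    weights = runif(arity, -1, 1),
                    m = runif(1, 0, 1),
                    n_act = runif(1, 0.1, 1))
}

random_node <- function(feature_dim, config, depth = 1L) {
  random_subtree(feature_dim, config, budget = config$max_depth - depth + 1L,
                 allow_leaf = depth > 1L)
}

#' Create a random initial FNT population
#'
#' Trees are grown recursively: the root is always a function node, interior
#' nodes branch with probability 1/2 until `max_depth` forces a leaf.
#' Weights are drawn Uniform(-1, 1), activation centers Uniform(0, 1) and
#' widths Uniform(0.1, 1).
#'
#' @param config A [train_config()].
#' @param feature_dim Number of features leaves may reference.
#' @param seed Integer seed.
#' @return List of `population_size` trees.
#' @export
init_population <- function(config, feature_dim, seed = config$seed) {
  stopifnot(inherits(config, "train_config"))
  if (feature_dim < 1L) stop("feature_dim must be >= 1")
  with_seed(seed, lapply(seq_len(config$population_size), function(i)
    random_node(feature_dim, config)))
}

# --- fitness ----------------------------------------------------------------

score_fitness <- function(scores, y, type) {
  if (type == "rmse") {
    sqrt(mean((scores - y)^2))
  } else {
    1 - auc_rank(scores, y)
  }
}

make_fitness_fn <- function(X, y, config) {
  force(X); force(y)
  function(tree) score_fitness(eval_node(tree, X), y, config$fitness)
}

# --- genetic operators ------------------------------------------------------

# Enumerate subtree paths; a path is an integer vector of child indices
# (length 0 = the node itself).
node_paths <- function(node, prefix = integer(0)) {
  if (!is_function_node(node)) return(list(prefix))
  out <- list(prefix)
  for (j in seq_along(node$children)) {
    out <- c(out, node_paths(node$children[[j]], c(prefix, j)))
  }
  out
}

get_subtree <- function(node, path) {
  for (j in path) node <- node$children[[j]]
  node
}

set_subtree <- function(node, path, sub) {
  if (length(path) == 0L) return(sub)
  node$children[[path[1]]] <-
    set_subtree(node$children[[path[1]]], path[-1], sub)
  node
}

# Swap a random subtree of `a` for a random subtree of `b`; reject swaps that
# would break the depth cap or demote the root to a leaf.
crossover_trees <- function(a, b, config, tries = 8L) {
  for (t in seq_len(tries)) {
    pa <- node_paths(a)
    pb <- node_paths(b)
    path_a <- pa[[sample.int(length(pa), 1L)]]
    path_b <- pb[[sample.int(length(pb), 1L)]]
    donor <- get_subtree(b, path_b)
    if (length(path_a) == 0L && !is_function_node(donor)) next
    child <- set_subtree(a, path_a, donor)
    if (tree_depth(child) <= config$max_depth) return(child)
  }
  a
}

perturb_parameters <- function(node, sd = 0.2) {
  if (!is_function_node(node)) return(node)
  node$weights <- node$weights + rnorm(length(node$weights), 0, sd)
  node$m <- node$m + rnorm(1, 0, sd)
  node$n_act <- node$n_act + rnorm(1, 0, sd)
  node$children <- lapply(node$children, perturb_parameters, sd = sd)
  node
}

mutate_tree <- function(tree, feature_dim, config) {
  op <- sample.int(3L, 1L)
  if (op == 1L) { # replace a random subtree with a fresh random one
    paths <- node_paths(tree)
    path <- paths[[sample.int(length(paths), 1L)]]
    depth_here <- length(path) + 1L
    sub <- random_subtree(feature_dim, config,
                          budget = config$max_depth - depth_here + 1L,
                          allow_leaf = depth_here > 1L)
    set_subtree(tree, path, sub)
  } else if (op == 2L) { # re-point a random leaf at a new feature
    paths <- node_paths(tree)
    leaf_paths <- Filter(function(p) !is_function_node(get_subtree(tree, p)),
                         paths)
    if (length(leaf_paths) == 0L) return(perturb_parameters(tree))
    path <- leaf_paths[[sample.int(length(leaf_paths), 1L)]]
    set_subtree(tree, path, fnt_leaf(sample.int(feature_dim, 1L)))
  } else { # jitter all continuous parameters
    perturb_parameters(tree)
  }
}

tournament_pick <- function(fitness, k) {
  cand <- sample.int(length(fitness), min(k, length(fitness)))
  cand[which.min(fitness[cand])]
}

#' One generation of genetic-programming structure search
#'
#' Tournament selection, subtree crossover, mutation, and elitism (the best
#' input tree survives unchanged). All offspring respect the depth cap and
#' arity set.
#'
#' @param population List of `fnt_node` trees.
#' @param fitness_fn Function tree -> scalar fitness (minimized).
#' @param config A [train_config()].
#' @param feature_dim Feature dimension for leaf re-sampling.
#' @param seed Integer seed.
#' @return List with `population` (next generation), `fitness` (of the
#'   input population) and `best` (index of the elite).
#' @export
evolve_structure <- function(population, fitness_fn, config, feature_dim,
                             seed = config$seed) {
  stopifnot(length(population) >= 1L)
  fit <- vapply(population, fitness_fn, numeric(1))
  best <- which.min(fit)
  with_seed(seed, {
    nxt <- vector("list", length(population))
    nxt[[1L]] <- population[[best]] # elitism
    for (i in seq_along(population)[-1L]) {
      p1 <- population[[tournament_pick(fit, config$tournament_size)]]
      child <- if (runif(1) < config$crossover_rate) {
        p2 <- population[[tournament_pick(fit, config$tournament_size)]]
        crossover_trees(p1, p2, config)
      } else p1
      if (runif(1) < config$mutation_rate) {
        child <- mutate_tree(child, feature_dim, config)
      }
      nxt[[i]] <- child
    }
    list(population = nxt, fitness = fit, best = best)
  })
}

# --- parameter flattening + PSO --------------------------------------------

flatten_parameters <- function(node) {
  if (!is_function_node(node)) return(numeric(0))
  c(node$weights, node$m, node$n_act,
    unlist(lapply(node$children, flatten_parameters)))
}

inject_parameters <- function(node, theta) {
  rebuild <- function(nd, pos) {
    if (!is_function_node(nd)) return(list(node = nd, pos = pos))
    r <- length(nd$weights)
    nd$weights <- theta[pos:(pos + r - 1L)]
    nd$m <- theta[pos + r]
    nd$n_act <- theta[pos + r + 1L]
    pos <- pos + r + 2L
    for (j in seq_along(nd$children)) {
      res <- rebuild(nd$children[[j]], pos)
      nd$children[[j]] <- res$node
      pos <- res$pos
    }
    list(node = nd, pos = pos)
  }
  rebuild(node, 1L)$node
}

#' Tune all continuous parameters of a tree by particle swarm optimization
#'
#' Flattens every edge weight and activation `(m, n_act)` into one vector
#' and runs a standard constricted PSO (inertia 0.729, cognitive/social
#' coefficients 1.49445). The incumbent parameters seed one particle, so the
#' returned fitness is never worse than the input tree's.
#'
#' @param tree An `fnt_node` with at least one function node.
#' @param X Feature matrix (samples x features).
#' @param y 0/1 labels.
#' @param config A [train_config()].
#' @param seed Integer seed.
#' @return List with `tree` (best parameters injected) and `fitness`.
#' @export
optimize_parameters <- function(tree, X, y, config, seed = config$seed) {
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  theta0 <- flatten_parameters(tree)
  D <- length(theta0)
  if (D == 0L) {
    return(list(tree = tree,
                fitness = score_fitness(eval_node(tree, X), y, config$fitness)))
  }
  fit_of <- function(theta) {
    score_fitness(eval_node(inject_parameters(tree, theta), X), y,
                  config$fitness)
  }
  with_seed(seed, {
    S <- config$swarm_size
    lo <- -5; hi <- 5
    pos <- matrix(runif(S * D, lo, hi), nrow = S)
    pos[1L, ] <- theta0
    for (s in 2:min(S, 5)) pos[s, ] <- theta0 + rnorm(D, 0, 0.3)
    vel <- matrix(runif(S * D, -1, 1) * 0.1, nrow = S)
    pbest <- pos
    pfit <- apply(pos, 1L, fit_of)
    g <- which.min(pfit)
    gbest <- pos[g, ]; gfit <- pfit[g]
    w <- 0.729; c1 <- 1.49445; c2 <- 1.49445
    for (it in seq_len(config$swarm_iterations)) {
      r1 <- matrix(runif(S * D), nrow = S)
      r2 <- matrix(runif(S * D), nrow = S)
      vel <- w * vel + c1 * r1 * (pbest - pos) +
        c2 * r2 * (matrix(gbest, nrow = S, ncol = D, byrow = TRUE) - pos)
      vel <- pmin(pmax(vel, -2), 2)
      pos <- pmin(pmax(pos + vel, lo), hi)
      newfit <- apply(pos, 1L, fit_of)
      upd <- newfit < pfit
      pbest[upd, ] <- pos[upd, , drop = FALSE]
      pfit[upd] <- newfit[upd]
      g <- which.min(pfit)
      if (pfit[g] < gfit) { gbest <- pbest[g, ]; gfit <- pfit[g] }
    }
    list(tree = inject_parameters(tree, gbest), fitness = gfit)
  })
}

#' Train a flexible neural tree classifier
#'
#' Alternates one GP generation of structure search with a PSO pass over the
#' parameters of the current best tree, for `config$generations` rounds.
#' Fully deterministic given `(X, y, config, seed)`: the master seed is
#' split into named substreams for initialization, per-generation evolution
#' and per-generation swarms.
#'
#' @param X Feature matrix (samples x features), or a `peptide_dataset`
#'   together with `encoder` arguments via [fnt_pipeline()].
#' @param y Binary labels (0/1, logical, or "positive"/"negative").
#' @param config A [train_config()].
#' @param seed Master seed; defaults to `config$seed`.
#' @return An `fnt_model`: list with `root`, `feature_dim`,
#'   `threshold` (0.5), `config`, `seed`, `fitness` and a per-generation
#'   `history` data.frame.
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(60, 2), 30), matrix(rnorm(60, -2), 30))
#' y <- rep(c(1, 0), each = 30)
#' m <- train_fnt(X, y, train_config(generations = 3), seed = 7)
#' mean((predict(m, X)$label == 1) == (y == 1))
#' @export
train_fnt <- function(X, y, config = train_config(), seed = config$seed) {
  stopifnot(inherits(config, "train_config"))
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2L) stop("training labels must contain both classes")
  if (min(table(y)) < 2L) stop("need at least 2 samples per class")
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))

  seeds <- derive_seeds(seed, 1L + 2L * config$generations)
  fitness_fn <- make_fitness_fn(X, y, config)
  pop <- init_population(config, ncol(X), seed = seeds[1L])

  best_tree <- NULL
  best_fit <- Inf
  history <- data.frame(generation = integer(0), best_fitness = numeric(0))
  for (g in seq_len(config$generations)) {
    step <- evolve_structure(pop, fitness_fn, config, ncol(X),
                             seed = seeds[2L * g])
    pop <- step$population
    # PSO on this generation's elite (population slot 1)
    tuned <- optimize_parameters(pop[[1L]], X, y, config,
                                 seed = seeds[2L * g + 1L])
    pop[[1L]] <- tuned$tree
    if (tuned$fitness < best_fit) {
      best_fit <- tuned$fitness
      best_tree <- tuned$tree
    }
    history <- rbind(history,
                     data.frame(generation = g, best_fitness = best_fit))
  }
  structure(list(root = best_tree, feature_dim = ncol(X), threshold = 0.5,
                 config = config, seed = seed, fitness = best_fit,
                 history = history),
            class = "fnt_model")
}

as_binary_labels <- function(y) {
  if (is.character(y) || is.factor(y)) {
    as.integer(as.character(y) == "positive")
  } else {
    as.integer(as.numeric(y) != 0)
  }
}

#' Predict acetylation scores and labels
#'
#' @param object An `fnt_model`.
#' @param features Feature matrix or single feature vector.
#' @param ... Unused.
#' @return data.frame with `score` in `(0, 1]` and `label` (1 if
#'   `score >= threshold`; a score exactly at the threshold is positive).
#' @export
predict.fnt_model <- function(object, features, ...) {
  s <- eval_tree(object, features)
  data.frame(score = s, label = as.integer(s >= object$threshold))
}
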