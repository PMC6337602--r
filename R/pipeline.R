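#' Standard FNT scoring pipeline for cross-validation and scans
#'
#' Returns a closure `(x_train, y_train, x_test, seed)` that globally
#' centers and scales the features (one mean and one standard deviation for
#' the whole training matrix — per-column scaling would erase the positional
#' influence weights the encoders put in), trains an FNT, and returns scores
#' for the test split.
#'
#' @param config A [train_config()].
#' @return A pipeline function usable with [kfold_cv()],
#'   [recover_family()], [scan_bandwidth()] and [search_params()].
#' @export
fnt_pipeline <- function(config = train_config()) {
  force(config)
  function(x_train, y_train, x_test, seed = config$seed) {
    mu <- mean(x_train)
    sc <- stats::sd(as.numeric(x_train))
    if (!is.finite(sc) || sc == 0) sc <- 1
    model <- train_fnt((x_train - mu) / sc, y_train, config, seed = seed)
    eval_tree(model, (x_test - mu) / sc)
  }
}

#' Hold-out evaluation of an encoder + FNT configuration
#'
#' Stratified single split: trains on `1 - holdout` of the data and reports
#' metrics on the rest.
#'
#' @param features Feature matrix.
#' @param labels Binary labels.
#' @param config A [train_config()].
#' @param holdout Held-out fraction (default 0.3).
#' @param seed Integer seed (split + training).
#' @return List with `report` (a `metrics_report` including AUC), `roc`
#'   (held-out `roc_curve`), and `model` (the trained `fnt_model`).
#' @export
holdout_eval <- function(features, labels, config = train_config(),
                         holdout = 0.3, seed = 1L) {
  y <- as_binary_labels(labels)
  X <- as.matrix(features)
  k <- max(2L, round(1 / holdout))
  seeds <- derive_seeds(seed, 2L)
  folds <- stratified_folds(y, k, seeds[1L])
  te <- folds == 1L
  pipe <- fnt_pipeline(config)
  mu <- mean(X[!te, ]); sc <- stats::sd(as.numeric(X[!te, ]))
  if (!is.finite(sc) || sc == 0) sc <- 1
  model <- train_fnt((X[!te, , drop = FALSE] - mu) / sc, y[!te], config,
                     seed = seeds[2L])
  s <- eval_tree(model, (X[te, , drop = FALSE] - mu) / sc)
  cc <- confusion(y[te], as.integer(s >= model$threshold))
  list(report = metrics_standard(cc, auc = auc_rank(s, y[te])),
       roc = roc_curve(s, y[te]),
       model = model)
}

#' Scan window bandwidths by cross-validated performance
#'
#' Evaluates each half-width `n` in `n_values` (bandwidth `2n + 1`; the
#' default 10..15 covers bandwidths 21, 23, 25, 27, 29, 31) by trimming the
#' dataset, encoding with `encoder_spec`, and running stratified k-fold CV
#' with the supplied pipeline. The best bandwidth is flagged by mean AUC,
#' ties broken toward the smaller `n` (cheaper features).
#'
#' @param dataset A `peptide_dataset` whose half-width is at least
#'   `max(n_values)`.
#' @param n_values Half-widths to scan (default `10:15`).
#' @param encoder_spec An [influence_spec()]; default the unit quadratic
#'   shape.
#' @param table Property table.
#' @param pipeline Scoring pipeline; default [fnt_pipeline()].
#' @param k CV folds (default 2).
#' @param seed Integer seed.
#' @param reduce Feature reduction (default `"sum"`).
#' @return data.frame with one row per `n`: `n`, `bandwidth`, mean
#'   `sensitivity`, `specificity`, `accuracy`, `f1`, `mcc`, `auc`, and
#'   `best` (logical flag). Attribute `"best_n"` holds the winner.
#' @export
scan_bandwidth <- function(dataset, n_values = 10:15,
                           encoder_spec = unit_influence_spec("quadratic"),
                           table = default_property_table(),
                           pipeline = fnt_pipeline(),
                           k = 2L, seed = 1L, reduce = "sum") {
  if (length(n_values) == 0L) stop("bandwidth scan set is empty")
  if (max(n_values) > dataset$spec$n) {
    stop(sprintf("dataset half-width (%d) is smaller than scan maximum (%d)",
                 dataset$spec$n, max(n_values)))
  }
  y <- dataset_labels(dataset)
  rows <- lapply(sort(n_values), function(n) {
    ds <- trim_dataset(dataset, n)
    iv <- influence_vector(encoder_spec, n)
    X <- encode_windows(ds, table, iv, reduce = reduce)
    cv <- kfold_cv(X, y, k, pipeline, seed = seed)
    mets <- colMeans(do.call(rbind, lapply(cv$fold_reports, function(r)
      unlist(unclass(r)))))
    data.frame(n = n, bandwidth = 2L * n + 1L,
               sensitivity = mets[["sensitivity"]],
               specificity = mets[["specificity"]],
               accuracy = mets[["accuracy"]], f1 = mets[["f1"]],
               mcc = mets[["mcc"]], auc = cv$mean_auc)
  })
  out <- do.call(rbind, rows)
  best_i <- which(out$auc == max(out$auc))[1L] # sorted by n: tie -> smaller
  out$best <- seq_len(nrow(out)) == best_i
  attr(out, "best_n") <- out$n[best_i]
  out
}

#' Grid-search influence-family coefficients by cross-validated AUC
#'
#' Evaluates every candidate coefficient combination of every family on a
#' grid inside the conventional ranges (`a` in `[-10, 10]`, `b`/`c` in
#' `[-100, 100]`) and returns the full score table plus the best
#' specification. Note that for the constant family the CV score is
#' invariant to `c1` (feature normalization absorbs a global scale), so all
#' grid points tie and the first is reported.
#'
#' @param dataset A `peptide_dataset`.
#' @param families Families to search.
#' @param grid Named list of coefficient grids, with elements `c1`, `a1`,
#'   `b1`, `a2`, `b2` (numeric vectors). Defaults to a coarse 5-point grid
#'   per coefficient within the conventional ranges.
#' @param table Property table.
#' @param pipeline Scoring pipeline; default [fnt_pipeline()].
#' @param k CV folds (default 2).
#' @param seed Integer seed.
#' @param reduce Feature reduction (default `"sum"`).
#' @return data.frame with columns `family`, `c1`, `a1`, `b1`, `a2`, `b2`
#'   (NA where not applicable) and `auc`, sorted by decreasing AUC;
#'   attribute `"best"` holds the winning [influence_spec()].
#' @export
search_params <- function(dataset,
                          families = c("constant", "sqrt", "quadratic"),
                          grid = NULL,
                          table = default_property_table(),
                          pipeline = fnt_pipeline(),
                          k = 2L, seed = 1L, reduce = "sum") {
  grid <- grid %||% list(c1 = seq(-100, 100, length.out = 5),
                         a1 = seq(-10, 10, length.out = 5),
                         b1 = seq(-100, 100, length.out = 5),
                         a2 = seq(-10, 10, length.out = 5),
                         b2 = seq(-100, 100, length.out = 5))
  candidates <- list()
  for (fam in families) {
    if (fam == "constant") {
      for (c1 in grid$c1) {
        if (c1 == 0) next # zero influence encodes nothing
        candidates[[length(candidates) + 1L]] <-
          influence_spec("constant", c1 = c1)
      }
    } else if (fam == "sqrt") {
      for (a1 in grid$a1) for (b1 in grid$b1) {
        if (a1 == 0 && b1 == 0) next
        candidates[[length(candidates) + 1L]] <-
          influence_spec("sqrt", a1 = a1, b1 = b1)
      }
    } else if (fam == "quadratic") {
      for (a2 in grid$a2) for (b2 in grid$b2) {
        if (a2 == 0 && b2 == 0) next
        candidates[[length(candidates) + 1L]] <-
          influence_spec("quadratic", a2 = a2, b2 = b2)
      }
    } else stop("unknown family: ", fam)
  }
  if (length(candidates) == 0L) stop("empty coefficient grid")

  y <- dataset_labels(dataset)
  n <- dataset$spec$n
  rows <- lapply(candidates, function(spec) {
    iv <- influence_vector(spec, n)
    X <- encode_windows(dataset, table, iv, reduce = reduce)
    auc <- kfold_cv(X, y, k, pipeline, seed = seed)$mean_auc
    data.frame(family = spec$family,
               c1 = spec$c1 %||% NA_real_, a1 = spec$a1 %||% NA_real_,
               b1 = spec$b1 %||% NA_real_, a2 = spec$a2 %||% NA_real_,
               b2 = spec$b2 %||% NA_real_, auc = auc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$auc)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "best") <- candidates[[ord[1L]]]
  out
}
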