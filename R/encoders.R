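#' Specify a polynomial positional-influence family
#'
#' The influence of a neighboring residue on the central lysine is modeled
#' as an even function of its signed offset `k` in `-n..n`:
#' \describe{
#'   \item{constant}{`c1` at every offset — all neighbors weigh equally, so
#'     pooled encoding reduces to (property-weighted) composition.}
#'   \item{sqrt}{`a1 * |k|^(1/2) + b1` — influence grows slowly away from
#'     the center.}
#'   \item{quadratic}{`a2 * k^2 + b2` — influence changes fastest at the
#'     window edges.}
#' }
#' Only the even families are admissible because upstream and downstream
#' flanks play symmetric roles around the modified residue. Coefficient
#' defaults are values that performed well when tuned on acetylation
#' benchmarks; the conventional search ranges are `a` in `[-10, 10]` and
#' `b`, `c` in `[-100, 100]`.
#'
#' @param family One of `"constant"`, `"sqrt"`, `"quadratic"`.
#' @param c1 Constant-family level.
#' @param a1,b1 Square-root-family slope and intercept.
#' @param a2,b2 Quadratic-family curvature and intercept.
#' @return An object of class `influence_spec`.
#' @examples
#' influence_spec("quadratic", a2 = 1, b2 = 0)
#' @export
influence_spec <- function(family = c("constant", "sqrt", "quadratic"),
                           c1 = 57.6, a1 = 4.1, b1 = 27.1,
                           a2 = -2.7, b2 = 67.1) {
  family <- match.arg(family)
  coef <- switch(family,
    constant = list(c1 = c1),
    sqrt = list(a1 = a1, b1 = b1),
    quadratic = list(a2 = a2, b2 = b2))
  if (any(!vapply(coef, is.finite, logical(1)))) {
    stop("influence coefficients must be finite")
  }
  structure(c(list(family = family), coef), class = "influence_spec")
}

#' @export
print.influence_spec <- function(x, ...) {
  coef <- unlist(x[-1])
  cat(sprintf("<influence_spec> %s: %s\n", x$family,
              paste(names(coef), signif(coef, 5), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Realize an influence specification as a positional weight vector
#'
#' Evaluates the family at the integer offsets `-n..n`. The result is always
#' an even (symmetric) vector of length `2n + 1`, named by offset.
#'
#' @param spec An [influence_spec()].
#' @param n Window half-width (positive integer).
#' @return Named numeric vector of length `2n + 1`, class `influence_vector`.
#' @examples
#' influence_vector(influence_spec("quadratic", a2 = 1, b2 = 0), 2)
#' @export
influence_vector <- function(spec, n) {
  stopifnot(inherits(spec, "influence_spec"))
  if (length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a single positive integer")
  }
  k <- seq.int(-n, n)
  v <- switch(spec$family,
    constant = rep(spec$c1, length(k)),
    sqrt = spec$a1 * sqrt(abs(k)) + spec$b1,
    quadratic = spec$a2 * k^2 + spec$b2)
  names(v) <- k
  class(v) <- c("influence_vector", "numeric")
  v
}

#' @export
print.influence_vector <- function(x, ...) {
  print(signif(unclass(x), 5))
  invisible(x)
}

windows_of <- function(x) {
  if (inherits(x, "peptide_dataset")) x$windows$window
  else if (is.data.frame(x)) x$window
  else as.character(x)
}

# n_windows x (2n+1) residue character matrix
residue_matrix <- function(windows) {
  len <- unique(nchar(windows))
  if (length(len) != 1L) stop("windows must all share one length")
  matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
         nrow = length(windows), ncol = len, byrow = TRUE)
}

#' Encode peptide windows with influence-weighted residue properties
#'
#' Feature `(p, k)` is `influence[k] * table[p, residue at offset k]` —
#' the positional influence profile elementwise with each property profile,
#' concatenated property-major. `"X"` contributes 0 wherever it occurs.
#' With the constant family at `c1 = 1` this is exactly the unweighted
#' property profile.
#'
#' Set `reduce = "sum"` to pool positions per property
#' (`sum_k influence[k] * table[p, residue_k]`), giving a compact
#' `P`-dimensional encoding in which the influence profile acts as a
#' positional matched filter; under a constant influence and a single
#' indicator-style property this reduces to amino-acid composition.
#'
#' @param windows A `peptide_dataset`, a data.frame with a `window` column,
#'   or a character vector of equal-length windows.
#' @param table A `property_table`.
#' @param influence An `influence_vector` of matching length.
#' @param reduce `"none"` (default, per-position features, length
#'   `P * (2n+1)`) or `"sum"` (length `P`).
#' @return Numeric feature matrix, one row per window; columns named
#'   `<property>@<offset>` or `<property>`.
#' @examples
#' tab <- default_property_table()
#' iv <- influence_vector(influence_spec("quadratic", a2 = 1, b2 = 0), 2)
#' encode_windows("AAKAA", tab, iv)[, 1:5]
#' @export
encode_windows <- function(windows, table, influence,
                           reduce = c("none", "sum")) {
  reduce <- match.arg(reduce)
  w <- windows_of(windows)
  res <- residue_matrix(w)
  if (ncol(res) != length(influence)) {
    stop(sprintf("influence length (%d) does not match window length (%d)",
                 length(influence), ncol(res)))
  }
  iv <- as.numeric(influence)
  idx <- match(res, AA_ALPHABET) # NA for 'X'
  tabv <- unclass(table)
  P <- nrow(tabv)
  offs <- seq.int(-(ncol(res) - 1L) / 2L, (ncol(res) - 1L) / 2L)
  blocks <- vector("list", P)
  for (p in seq_len(P)) {
    vals <- tabv[p, idx]
    vals[is.na(vals)] <- 0
    m <- matrix(vals, nrow = nrow(res), ncol = ncol(res))
    m <- sweep(m, 2L, iv, `*`)
    if (reduce == "sum") {
      blocks[[p]] <- matrix(rowSums(m), ncol = 1,
                            dimnames = list(NULL, rownames(tabv)[p]))
    } else {
      colnames(m) <- paste0(rownames(tabv)[p], "@", offs)
      blocks[[p]] <- m
    }
  }
  out <- do.call(cbind, blocks)
  if (any(!is.finite(out))) stop("non-finite feature values")
  rownames(out) <- if (is.data.frame(windows) ||
                       inherits(windows, "peptide_dataset")) NULL else NULL
  out
}

#' Encode a single window (influence-weighted properties)
#'
#' Convenience wrapper around [encode_windows()] for one window.
#'
#' @inheritParams encode_windows
#' @param window A single window string.
#' @return Named numeric vector.
#' @export
encode_window <- function(window, table, influence,
                          reduce = c("none", "sum")) {
  stopifnot(length(window) == 1L)
  encode_windows(window, table, influence, reduce)[1, ]
}

#' One-hot (binary) window encoding
#'
#' Twenty indicator features per position; `"X"` yields an all-zero block.
#'
#' @param windows Windows as in [encode_windows()].
#' @return Numeric matrix, `20 * (2n+1)` columns named `<residue>@<offset>`.
#' @export
encode_binary <- function(windows) {
  w <- windows_of(windows)
  res <- residue_matrix(w)
  L <- ncol(res)
  offs <- seq.int(-(L - 1L) / 2L, (L - 1L) / 2L)
  out <- matrix(0, nrow = nrow(res), ncol = 20L * L)
  colnames(out) <- paste0(rep(AA_ALPHABET, times = L), "@",
                          rep(offs, each = 20L))
  hit <- matrix(match(res, AA_ALPHABET), nrow = nrow(res))
  for (j in seq_len(L)) {
    h <- hit[, j]
    ok <- !is.na(h)
    out[cbind(which(ok), (j - 1L) * 20L + h[ok])] <- 1
  }
  out
}

# Default residue grouping for the grouped composition encoder.
aa_groups_default <- function() {
  list(hydrophobic = c("A", "V", "L", "I", "M", "F", "W"),
       polar = c("S", "T", "Y", "N", "Q"),
       charged = c("D", "E", "K", "R", "H"),
       special = c("C", "G", "P"))
}

#' Amino-acid composition encoding
#'
#' Residue (or residue-group) frequencies among non-`"X"` positions; rows
#' sum to 1.
#'
#' @param windows Windows as in [encode_windows()].
#' @param grouped Use the 4-group scheme (hydrophobic / polar / charged /
#'   special) instead of 20 residues.
#' @param groups Optional named list of character vectors partitioning
#'   [AA_ALPHABET], used when `grouped = TRUE`.
#' @return Numeric matrix with 20 (or `length(groups)`) columns.
#' @export
encode_aac <- function(windows, grouped = FALSE, groups = aa_groups_default()) {
  w <- windows_of(windows)
  res <- residue_matrix(w)
  denom <- rowSums(matrix(res %in% AA_ALPHABET, nrow = nrow(res)))
  if (any(denom == 0)) stop("window(s) consisting only of 'X' cannot be encoded")
  if (grouped) {
    if (!setequal(unlist(groups), AA_ALPHABET)) {
      stop("`groups` must partition the 20-residue alphabet")
    }
    out <- vapply(groups, function(g) {
      rowSums(matrix(res %in% g, nrow = nrow(res))) / denom
    }, numeric(nrow(res)))
    out <- matrix(out, nrow = nrow(res),
                  dimnames = list(NULL, names(groups)))
  } else {
    out <- vapply(AA_ALPHABET, function(a) {
      rowSums(res == a) / denom
    }, numeric(nrow(res)))
    out <- matrix(out, nrow = nrow(res), dimnames = list(NULL, AA_ALPHABET))
  }
  out
}

#' Mean physico-chemical property encoding
#'
#' Per property, the arithmetic mean of residue property values over
#' non-`"X"` positions.
#'
#' @param windows Windows as in [encode_windows()].
#' @param table A `property_table`.
#' @return Numeric matrix with `P` columns.
#' @export
encode_physchem_mean <- function(windows, table) {
  w <- windows_of(windows)
  res <- residue_matrix(w)
  denom <- rowSums(matrix(res %in% AA_ALPHABET, nrow = nrow(res)))
  if (any(denom == 0)) stop("window(s) consisting only of 'X' cannot be encoded")
  idx <- match(res, AA_ALPHABET)
  tabv <- unclass(table)
  out <- matrix(0, nrow = nrow(res), ncol = nrow(tabv),
                dimnames = list(NULL, rownames(tabv)))
  for (p in seq_len(nrow(tabv))) {
    vals <- tabv[p, idx]
    vals[is.na(vals)] <- 0
    out[, p] <- rowSums(matrix(vals, nrow = nrow(res))) / denom
  }
  out
}

#' Write a feature matrix with window identifiers and labels as TSV
#'
#' @param features Numeric matrix from an encoder.
#' @param dataset The `peptide_dataset` the features came from.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, dataset, path) {
  df <- data.frame(protein_id = dataset$windows$protein_id,
                   position = dataset$windows$position,
                   label = dataset$windows$label,
                   features, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#'
#' @param path TSV path.
#' @return List with `features` (numeric matrix), `labels` (0/1 integer),
#'   and `meta` (data.frame `protein_id`, `position`, `label`).
#' @export
read_features <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("protein_id", "position", "label")
  stopifnot(all(meta_cols %in% names(df)))
  feats <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  mode(feats) <- "numeric"
  list(features = feats,
       labels = as.integer(df$label == "positive"),
       meta = df[, meta_cols])
}
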