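#' AAIndex accessions of the default physico-chemical property set
#'
#' Thirteen AAIndex entries covering charge, hydrophobicity, surface
#' accessibility, flexibility, mutability and secondary-structure propensity
#' — a compact panel with a track record in lysine-modification prediction.
#'
#' @return Named character vector: accession -> short description.
#' @export
acetyl_property_ids <- function() {
  c(CHOP780207 = "Normalized frequency of C-terminal non-helical region",
    DAYM780201 = "Relative mutability",
    EISD860102 = "Atom-based hydrophobic moment",
    FAUJ880108 = "Localized electrical effect",
    FAUJ880111 = "Positive charge",
    FINA910103 = "Helix termination parameter at position j-2, j-1, j",
    JANJ780101 = "Average accessible surface area",
    KARP850103 = "Flexibility parameter for two rigid neighbors",
    KLEP840101 = "Net charge",
    KRIW710101 = "Side-chain interaction parameter",
    KRIW790102 = "Fraction of site occupied by water",
    NAKH920103 = "AA composition of ejecta of single-spanning proteins",
    QIAN880101 = "Weights for alpha-helix at the window position of -6")
}

new_property_table <- function(values, standardized) {
  stopifnot(is.matrix(values), ncol(values) == 20L,
            identical(colnames(values), AA_ALPHABET))
  if (any(!is.finite(values))) stop("property table contains non-finite values")
  structure(values, class = c("property_table", class(values)),
            standardized = standardized)
}

#' Build the default residue property table from the AAIndex database
#'
#' Looks the accessions up in the AAIndex copy shipped with seqinr and
#' returns a P x 20 matrix (properties in rows, residues in columns, ordered
#' as [AA_ALPHABET]).
#'
#' @param ids AAIndex accessions; defaults to [acetyl_property_ids()].
#' @param standardize If `TRUE` (default) each property row is z-scored
#'   across the 20 residues, so no single AAIndex entry dominates by scale.
#' @return A `property_table` (numeric matrix with a `standardized`
#'   attribute).
#' @examples
#' tab <- default_property_table()
#' dim(tab)
#' @export
default_property_table <- function(ids = names(acetyl_property_ids()),
                                   standardize = TRUE) {
  aaindex <- NULL # bound by data() below
  utils::data("aaindex", package = "seqinr", envir = environment())
  acc <- vapply(aaindex, function(e) e$H, character(1))
  hit <- match(ids, acc)
  if (anyNA(hit)) {
    stop("AAIndex accession(s) not found: ",
         paste(ids[is.na(hit)], collapse = ", "))
  }
  rows <- lapply(aaindex[hit], function(e) {
    v <- e$I
    one <- toupper(vapply(names(v), function(nm) seqinr::a(nm), character(1)))
    v[match(AA_ALPHABET, one)]
  })
  values <- do.call(rbind, rows)
  dimnames(values) <- list(ids, AA_ALPHABET)
  tab <- new_property_table(values, standardized = FALSE)
  if (standardize) standardize_properties(tab) else tab
}

#' Z-score each property across the 20 residues
#'
#' @param table A `property_table`.
#' @return A `property_table` with every row at mean 0, unit variance.
#' @export
standardize_properties <- function(table) {
  v <- unclass(table)
  m <- rowMeans(v)
  s <- apply(v, 1, stats::sd)
  if (any(s == 0)) stop("constant property row cannot be standardized")
  new_property_table((v - m) / s, standardized = TRUE)
}

#' Read a residue property table from TSV/CSV
#'
#' Expected layout: a header of one-letter residue codes, a first column of
#' property identifiers, one row per property. All 20 standard residues must
#' be present.
#'
#' @param path File path; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @param standardize Z-score rows after reading (default `TRUE`).
#' @return A `property_table`.
#' @export
read_property_table <- function(path, standardize = TRUE) {
  if (!file.exists(path)) stop("property table not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  ids <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  missing <- setdiff(AA_ALPHABET, colnames(mat))
  if (length(missing) > 0L) {
    stop("property table lacks residue column(s): ",
         paste(missing, collapse = ", "))
  }
  mat <- mat[, AA_ALPHABET, drop = FALSE]
  rownames(mat) <- ids
  tab <- new_property_table(mat, standardized = FALSE)
  if (standardize) standardize_properties(tab) else tab
}

#' Write a property table to TSV
#'
#' @param table A `property_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_property_table <- function(table, path) {
  df <- data.frame(property = rownames(table), unclass(table),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.property_table <- function(x, ...) {
  cat(sprintf("<property_table> %d properties x 20 residues (%s)\n",
              nrow(x),
              if (isTRUE(attr(x, "standardized"))) "standardized" else "raw"))
  print(utils::head(unclass(x), 3))
  if (nrow(x) > 3) cat("...\n")
  invisible(x)
}

# Property values for a character vector of residues; 'X' (or anything not in
# the alphabet) contributes 0.
property_profile <- function(table, property, residues) {
  v <- unclass(table)[property, ]
  out <- v[match(residues, AA_ALPHABET)]
  out[is.na(out)] <- 0
  unname(out)
}
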