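#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased on read. Characters outside the 20-letter amino
#' acid alphabet (including the ambiguity codes B, Z, J and the rare residues
#' U, O, and `*` stops) are mapped to `"X"` with a warning, so that downstream
#' encoders can treat them uniformly as property-neutral positions.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A data.frame with columns `id` (first whitespace-delimited header
#'   token) and `sequence`. Zero rows for a file without records.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "AAKAA"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(startsWith(lines, ">"))) {
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  hdr <- which(startsWith(lines, ">"))
  body_len <- diff(c(hdr, length(lines) + 1L)) - 1L
  has_body <- vapply(seq_along(hdr), function(i) {
    if (body_len[i] == 0L) return(FALSE)
    any(nzchar(trimws(lines[(hdr[i] + 1L):(hdr[i] + body_len[i])])))
  }, logical(1))
  if (any(!has_body)) {
    stop("FASTA format error: empty sequence for record(s) ",
         paste(sub("^>\\s*", "", lines[hdr[!has_body]]), collapse = ", "))
  }
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  ids <- vapply(recs, function(r) attr(r, "name"), character(1))
  seqs <- toupper(vapply(recs, function(r) as.character(r)[1], character(1)))
  if (any(!nzchar(seqs))) {
    stop("FASTA format error: empty sequence for record(s) ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  cleaned <- sanitize_sequences(seqs, ids)
  data.frame(id = unname(ids), sequence = unname(cleaned),
             stringsAsFactors = FALSE)
}

sanitize_sequences <- function(seqs, ids = NULL) {
  ok <- c(AA_ALPHABET, "X")
  bad_total <- 0L
  out <- vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- !(ch %in% ok)
    if (any(bad)) {
      bad_total <<- bad_total + sum(bad)
      ch[bad] <- "X"
    }
    paste(ch, collapse = "")
  }, character(1))
  if (bad_total > 0L) {
    warning(bad_total, " non-standard residue(s) mapped to 'X'")
  }
  out
}

#' Write protein records to FASTA
#'
#' @param proteins data.frame with columns `id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(c(paste0(">", proteins$id[i]), proteins$sequence[i]), con)
  }
  invisible(path)
}

#' Define a lysine-centered window specification
#'
#' A window spans `2n + 1` residues: `n` upstream, the central lysine, and
#' `n` downstream. Window length is called the bandwidth; the usual scan
#' range is bandwidth 21 to 31, i.e. `n` from 10 to 15.
#'
#' @param n Half-width (positive integer).
#' @return An object of class `window_spec` with elements `n` and `length`.
#' @examples
#' window_spec(12)
#' @export
window_spec <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n)) {
    stop("`n` must be a single positive integer")
  }
  structure(list(n = as.integer(n), length = 2L * as.integer(n) + 1L),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> half-width n = %d (bandwidth %d)\n",
              x$n, x$length))
  invisible(x)
}

#' Extract lysine-centered peptide windows from protein sequences
#'
#' One window per `K` residue. Windows overrunning either terminus are padded
#' with `"X"`, which all encoders treat as property value zero, so feature
#' dimensionality is constant across sites.
#'
#' @param proteins data.frame with columns `id`, `sequence` (or a single-row
#'   list with those fields).
#' @param spec A [window_spec()].
#' @return data.frame with columns `protein_id`, `position` (1-based index of
#'   the central lysine) and `window` (string of length `2n + 1`).
#' @examples
#' extract_windows(data.frame(id = "p1", sequence = "AAKAA"), window_spec(2))
#' @export
extract_windows <- function(proteins, spec) {
  stopifnot(inherits(spec, "window_spec"))
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  n <- spec$n
  out <- vector("list", nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    s <- proteins$sequence[i]
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    kpos <- which(ch == "K")
    if (length(kpos) == 0L) next
    padded <- c(rep("X", n), ch, rep("X", n))
    win <- vapply(kpos, function(p) {
      paste(padded[p:(p + 2L * n)], collapse = "")
    }, character(1))
    out[[i]] <- data.frame(protein_id = proteins$id[i], position = kpos,
                           window = win, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(protein_id = character(), position = integer(),
                      window = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Read acetylation-site annotations
#'
#' @param path TSV file with a header line and columns `protein_id` and
#'   `position` (1-based residue index of an acetylated lysine).
#' @return data.frame with columns `protein_id`, `position`.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein_id", "position") %in% names(df))) {
    stop("annotation file must have columns 'protein_id' and 'position'")
  }
  df$position <- as.integer(df$position)
  df[, c("protein_id", "position")]
}

#' Write acetylation-site annotations
#'
#' @param sites data.frame with columns `protein_id`, `position`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites[, c("protein_id", "position")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a labeled window dataset from sequences and site annotations
#'
#' Windows at annotated positions are labeled positive; every other lysine
#' window is a negative candidate. Because real acetylation data are heavily
#' imbalanced (roughly 15 negatives per positive), negatives are subsampled
#' without replacement to `negative_ratio` times the positive count, under
#' `seed`.
#'
#' @param proteins data.frame of protein records (see [read_fasta()]).
#' @param sites data.frame of annotations (see [read_sites()]).
#' @param spec A [window_spec()].
#' @param negative_ratio Positive number, or `"all"` to keep every negative.
#' @param seed Integer seed for the negative subsample.
#' @param bad_site `"error"` (default) rejects annotations that point at a
#'   non-lysine residue or fall outside the sequence, listing the offenders;
#'   `"skip"` drops them with a warning.
#' @return An object of class `peptide_dataset`: a list with `windows`
#'   (data.frame `protein_id`, `position`, `window`, `label` in
#'   `c("positive","negative")`), `spec`, and `provenance` (class counts,
#'   ratio, seed).
#' @examples
#' prot <- data.frame(id = "p1", sequence = "AAKAAAAKAA")
#' ann <- data.frame(protein_id = "p1", position = 3)
#' build_dataset(prot, ann, window_spec(2), negative_ratio = "all")
#' @export
build_dataset <- function(proteins, sites, spec, negative_ratio = 1,
                          seed = 1L, bad_site = c("error", "skip")) {
  bad_site <- match.arg(bad_site)
  stopifnot(inherits(spec, "window_spec"))
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  sites <- unique(sites[, c("protein_id", "position")])

  idx <- match(sites$protein_id, proteins$id)
  offenders <- character(0)
  keep <- rep(TRUE, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    if (is.na(idx[i])) {
      offenders <- c(offenders, sprintf("%s:%d (unknown protein)",
                                        sites$protein_id[i], sites$position[i]))
      keep[i] <- FALSE
      next
    }
    s <- proteins$sequence[idx[i]]
    p <- sites$position[i]
    if (is.na(p) || p < 1L || p > nchar(s)) {
      offenders <- c(offenders, sprintf("%s:%s (out of bounds)",
                                        sites$protein_id[i], p))
      keep[i] <- FALSE
    } else if (substr(s, p, p) != "K") {
      offenders <- c(offenders, sprintf("%s:%d (residue '%s', not 'K')",
                                        sites$protein_id[i], p,
                                        substr(s, p, p)))
      keep[i] <- FALSE
    }
  }
  if (length(offenders) > 0L) {
    msg <- paste0("invalid site annotation(s): ",
                  paste(offenders, collapse = "; "))
    if (bad_site == "error") stop(msg) else warning(msg)
  }
  sites <- sites[keep, , drop = FALSE]

  windows <- extract_windows(proteins, spec)
  wkey <- paste(windows$protein_id, windows$position)
  skey <- paste(sites$protein_id, sites$position)
  windows$label <- ifelse(wkey %in% skey, "positive", "negative")

  pos <- windows[windows$label == "positive", , drop = FALSE]
  neg <- windows[windows$label == "negative", , drop = FALSE]
  n_neg_all <- nrow(neg)
  if (!identical(negative_ratio, "all")) {
    stopifnot(is.numeric(negative_ratio), negative_ratio > 0)
    n_keep <- min(n_neg_all, round(negative_ratio * nrow(pos)))
    neg <- with_seed(seed, neg[sample.int(n_neg_all, n_keep), , drop = FALSE])
  }
  windows <- rbind(pos, neg)
  rownames(windows) <- NULL

  structure(list(
    windows = windows,
    spec = spec,
    provenance = list(n_positive = nrow(pos), n_negative = nrow(neg),
                      n_negative_candidates = n_neg_all,
                      negative_ratio = negative_ratio, seed = seed)
  ), class = "peptide_dataset")
}

#' @export
print.peptide_dataset <- function(x, ...) {
  cat(sprintf(paste0("<peptide_dataset> %d windows (bandwidth %d): ",
                     "%d positive, %d negative\n"),
              nrow(x$windows), x$spec$length,
              x$provenance$n_positive, x$provenance$n_negative))
  invisible(x)
}

#' Binary labels of a peptide dataset
#'
#' @param dataset A `peptide_dataset`.
#' @return Integer vector, 1 for positive windows and 0 for negative.
#' @export
dataset_labels <- function(dataset) {
  as.integer(dataset$windows$label == "positive")
}

#' Trim a window dataset to a narrower half-width
#'
#' Cuts every window symmetrically around the central lysine, so one wide
#' extraction can be reused for a bandwidth scan without re-reading the
#' sequences.
#'
#' @param dataset A `peptide_dataset`.
#' @param n_new New half-width, at most the current one.
#' @return A `peptide_dataset` with half-width `n_new`.
#' @export
trim_dataset <- function(dataset, n_new) {
  n_old <- dataset$spec$n
  stopifnot(n_new >= 1, n_new <= n_old)
  if (n_new == n_old) return(dataset)
  from <- n_old - n_new + 1L
  to <- n_old + n_new + 1L
  dataset$windows$window <- substr(dataset$windows$window, from, to)
  dataset$spec <- window_spec(n_new)
  dataset
}

#' Export a labeled dataset as TSV
#'
#' Columns: `protein_id`, `position`, `window`, `label`.
#'
#' @param dataset A `peptide_dataset`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.table(dataset$windows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a labeled dataset from TSV
#'
#' @param path TSV written by [write_dataset()].
#' @return A `peptide_dataset`. The window spec is inferred from window
#'   length; provenance records observed class counts.
#' @export
read_dataset <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "position", "window", "label") %in% names(df)))
  len <- unique(nchar(df$window))
  if (length(len) != 1L || len %% 2L != 1L) {
    stop("windows must all share one odd length")
  }
  structure(list(
    windows = df,
    spec = window_spec((len - 1L) / 2L),
    provenance = list(n_positive = sum(df$label == "positive"),
                      n_negative = sum(df$label == "negative"),
                      negative_ratio = NA, seed = NA)
  ), class = "peptide_dataset")
}
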