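# Independent oracles and small fixtures used across the test files.

# Scalar, closed-form recursive FNT evaluator, written independently of the
# package's vectorized evaluator.
oracle_eval <- function(node, x) {
  if (identical(node$kind, "leaf")) return(x[node$feature])
  net <- 0
  for (j in seq_along(node$children)) {
    net <- net + node$weights[j] * oracle_eval(node$children[[j]], x)
  }
  exp(-((net - node$m) / max(abs(node$n_act), 1e-6))^2)
}

# Brute-force AUC: count positive-negative pairs, half credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# A tiny two-property table over the full alphabet, values 1..20 and 20..1.
toy_property_table <- function(standardize = FALSE) {
  path <- tempfile(fileext = ".tsv")
  vals <- rbind(p1 = seq_len(20), p2 = rev(seq_len(20)))
  df <- data.frame(property = rownames(vals), vals, check.names = FALSE)
  colnames(df)[-1] <- acetree::AA_ALPHABET
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  acetree::read_property_table(path, standardize = standardize)
}

# Single-property table with chosen values (named by residue; rest 0).
single_property_table <- function(values) {
  v <- setNames(rep(0, 20), acetree::AA_ALPHABET)
  v[names(values)] <- values
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(property = "p1", t(v), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  acetree::read_property_table(path, standardize = FALSE)
}

random_window <- function(n, alphabet = acetree::AA_ALPHABET) {
  ch <- sample(alphabet, 2 * n + 1, replace = TRUE)
  ch[n + 1] <- "K"
  paste(ch, collapse = "")
}

write_temp_fasta <- function(ids, seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

with_seed_shuffle <- function(x, seed) {
  set.seed(seed)
  x[sample.int(length(x))]
}

# Small, fast training configuration for tests that fit models repeatedly.
fast_config <- function(...) {
  acetree::train_config(population_size = 12L, generations = 4L,
                        swarm_size = 10L, swarm_iterations = 10L, ...)
}
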