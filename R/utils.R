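# Internal helpers shared across modules.

# Canonical key for a (miRNA, gene) pair. "\t" cannot occur in ids read from
# delimited tables, so the key is collision-free.
pair_key <- function(mirna_id, gene_id) {
  paste(mirna_id, gene_id, sep = "\t")
}

# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# inverse logit, safe for large |x|
inv_logit <- function(x) 1 / (1 + exp(-x))

# Deterministic ordering of interactions: score descending, ties broken
# lexicographically by pair id so that no label information leaks into
# position-dependent quantities.
score_order <- function(norm_score, mirna_id, gene_id) {
  order(-norm_score, mirna_id, gene_id, method = "radix")
}

# Derive a 32-bit sub-seed from a master seed and a stream index.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483647L)
}

msg <- function(..., verbose = getOption("mirfuse.verbose", TRUE)) {
  if (isTRUE(verbose)) message(...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
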