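# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except the frozen exact-arithmetic oracle table.

# Build a scored_db from parallel vectors (norm_score optional).
make_db <- function(name, mirna, gene, raw, norm = NULL,
                    direction = "higher_is_better", level = "gene") {
  df <- data.frame(mirna_id = mirna, gene_id = gene, raw_score = raw,
                   stringsAsFactors = FALSE)
  if (!is.null(norm)) df$norm_score <- norm
  scored_db(name, df, direction = direction, level = level)
}

# A gold standard from pair keys "mirna\tgene".
make_gold <- function(keys) {
  parts <- strsplit(keys, "\t", fixed = TRUE)
  gold_standard(test = data.frame(
    mirna_id = vapply(parts, `[`, "", 1L),
    gene_id = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE
  ))
}

keys_of <- function(db) paste(db$interactions$mirna_id,
                              db$interactions$gene_id, sep = "\t")

# Standard informative 3-database ensemble: expected AUCs 0.65/0.70/0.75
# (Beta(a,1) true scores against uniform false scores), gold = truth.
informative_spec <- function(seed, n_mirnas = 100L, n_genes = 200L,
                             n_true = 1200L, db_true = 800L,
                             db_false = 1600L, coverage = 1) {
  ensemble_spec(n_mirnas, n_genes, n_true, list(
    synthetic_db("dbA", db_true, db_false, auc = 0.65),
    synthetic_db("dbB", db_true, db_false, auc = 0.70),
    synthetic_db("dbC", db_true, db_false, auc = 0.75)
  ), validation_coverage = coverage, seed = seed)
}

# Independent brute-force AUC oracle: all positive/negative score
# comparisons, half credit for ties. O(n_pos * n_neg); small n only.
auc_bruteforce <- function(score, label) {
  sp <- score[label]
  sn <- score[!label]
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  mean(cmp)
}

# Rank-statistic AUC used as an oracle at larger n (midranks for ties).
auc_mannwhitney <- function(score, label) {
  r <- rank(score, ties.method = "average")
  np <- sum(label); nn <- sum(!label)
  (sum(r[label]) - np * (np + 1) / 2) / (np * nn)
}

# AUC against held-out truth: positives are true pairs the gold standard
# never confirmed, negatives are non-true universe pairs. Gold-confirmed
# pairs (used in fitting) are excluded, so the measurement is unbiased.
heldout_truth_auc <- function(cs, ens, universe) {
  pos <- universe$keys %in% setdiff(ens$truth, ens$gold$keys)
  neg <- !(universe$keys %in% ens$truth)
  keep <- pos | neg
  auc_mannwhitney(cs$scores[keep], pos[keep])
}

# Per-database AUC on its own covered pairs (the quantity expected_auc
# predicts when gold = truth).
own_pairs_auc <- function(db, gold) {
  lab <- keys_of(db) %in% gold$keys
  auc_mannwhitney(db$interactions$norm_score, lab)
}
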