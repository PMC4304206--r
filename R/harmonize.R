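#' Harmonize identifiers and collapse transcripts to genes
#'
#' Replaces miRNA and gene/transcript identifiers by their canonical forms
#' using alias dictionaries, then collapses transcript-level predictions to
#' the gene level. When the collapse (or the id unification) produces
#' duplicate (miRNA, gene) pairs, the most confident raw score is kept.
#' Identifiers absent from a dictionary pass through unchanged and are
#' counted in a message; matching is exact and case-preserving, so
#' dictionary gaps stay visible instead of being hidden by case folding.
#'
#' Applying the same maps twice is a no-op (canonical ids map to themselves).
#'
#' @param db A [scored_db()].
#' @param mirna_aliases An [alias_map()] for miRNA names, or `NULL`.
#' @param gene_map An [alias_map()] from transcript/source ids to gene ids,
#'   or `NULL`.
#' @return A gene-level `scored_db` with canonical ids and no duplicate
#'   pairs.
#' @export
harmonize <- function(db, mirna_aliases = NULL, gene_map = NULL) {
  stopifnot(inherits(db, "scored_db"))
  df <- db$interactions
  m <- apply_alias(df$mirna_id, mirna_aliases)
  g <- apply_alias(df$gene_id, gene_map)
  if (!is.null(mirna_aliases) && attr(m, "n_unmapped") > 0L) {
    msg("mirfuse: '", db$name, "': ", attr(m, "n_unmapped"),
        " miRNA id(s) not in the alias dictionary (kept as-is)")
  }
  if (!is.null(gene_map) && attr(g, "n_unmapped") > 0L) {
    msg("mirfuse: '", db$name, "': ", attr(g, "n_unmapped"),
        " gene/transcript id(s) not in the gene map (kept as-is)")
  }
  df$mirna_id <- as.character(m)
  df$gene_id <- as.character(g)
  df <- dedup_pairs(df, db$direction, db$name)
  rownames(df) <- NULL
  structure(list(name = db$name, interactions = df,
                 direction = db$direction, level = "gene"),
            class = "scored_db")
}
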