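#' Accumulated precision profile of a database
#'
#' Sorts a database's interactions from most to least confident and computes
#' the accumulated precision TP/(TP+FP) at every position: the fraction of
#' validated interactions among the top `i` after `i` positions. The profile
#' is then corrected by subtracting the database's expected precision — the
#' validated fraction a random ordering attains — and floored at zero, so
#' positions where the database performs at or below random carry no weight.
#'
#' Ties in the normalized score are broken lexicographically by pair id:
#' a label-blind, deterministic rule that cannot leak validation status into
#' the weights.
#'
#' @param db A normalized [scored_db()].
#' @param gold A [gold_standard()].
#' @return An object of class `precision_profile`: `db_name`, `keys` (pair
#'   keys in sorted order), `norm_score`, `validated`, `acc_precision`,
#'   `expected_precision`, `weight`.
#' @export
accumulated_precision <- function(db, gold) {
  stopifnot(inherits(db, "scored_db"), inherits(gold, "gold_standard"))
  df <- db$interactions
  if (!nrow(df)) stop("empty database")
  if (anyNA(df$norm_score)) stop("database '", db$name, "' must be normalized")
  ord <- score_order(df$norm_score, df$mirna_id, df$gene_id)
  keys <- pair_key(df$mirna_id, df$gene_id)[ord]
  val <- keys %in% gold$keys
  acc <- cumsum(val) / seq_along(val)
  expected <- sum(val) / length(val)
  structure(
    list(db_name = db$name, keys = keys, norm_score = df$norm_score[ord],
         validated = val, acc_precision = acc,
         expected_precision = expected,
         weight = pmax(acc - expected, 0)),
    class = "precision_profile"
  )
}

#' @export
print.precision_profile <- function(x, ...) {
  cat("<precision_profile> ", x$db_name, ": ", length(x$keys),
      " positions, expected precision ",
      format(x$expected_precision, digits = 4), ", ",
      sum(x$weight > 0), " with positive weight\n", sep = "")
  invisible(x)
}

#' Combine databases by precision-weighted score summation (WSP)
#'
#' For every pair in the universe, the combined score is the sum over the
#' databases containing the pair of the pair's normalized score multiplied by
#' that database's corrected accumulated precision *at the pair's own
#' position* in the database's sorted list. Pairs a database does not predict
#' contribute nothing from it. The construction gives high combined scores to
#' interactions that (a) score highly, (b) in databases performing above
#' random at that depth, and (c) are supported by several databases — while a
#' database whose ranking is uninformative gets weights near zero and cannot
#' drag down the others.
#'
#' @param dbs Non-empty list of normalized gene-level [scored_db()].
#' @param gold A [gold_standard()] (used to compute the precision weights;
#'   WSP is fit on the full gold standard).
#' @param universe A [build_universe()] over (at least) `dbs`.
#' @return A `combined_scores` object (method `"WSP"`) covering the whole
#'   universe, with per-pair supporting-database counts and the per-database
#'   [accumulated_precision()] profiles attached as `profiles`.
#' @export
wsp_combine <- function(dbs, gold, universe) {
  if (!length(dbs)) stop("at least one database is required")
  profiles <- lapply(dbs, accumulated_precision, gold = gold)
  all_keys <- unlist(lapply(profiles, `[[`, "keys"), use.names = FALSE)
  contrib <- unlist(lapply(profiles, function(p) p$norm_score * p$weight),
                    use.names = FALSE)
  idx <- match(all_keys, universe$keys)
  if (anyNA(idx)) stop("database pair outside the universe")
  scores <- numeric(length(universe$keys))
  sums <- rowsum(contrib, idx)
  scores[as.integer(rownames(sums))] <- sums[, 1L]
  support <- integer(length(universe$keys))
  tab <- rowsum(rep(1L, length(idx)), idx)
  support[as.integer(rownames(tab))] <- tab[, 1L]
  combined_scores("WSP", universe, scores, n_supporting = support,
                  extra = list(profiles = profiles))
}
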