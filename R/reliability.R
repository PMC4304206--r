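#' Log-space upper-tail hypergeometric probability
#'
#' Natural log of `P[X >= k]` where `X` is hypergeometric: `k` successes
#' drawn in a sample of size `n` from a population of `N` items of which `K`
#' are successes. The enrichment p-values in the database-reliability sweep
#' routinely underflow double precision (p below 1e-300), so the tail is
#' accumulated entirely in log space: each term
#' `C(K,i) C(N-K, n-i) / C(N,n)` is evaluated through log-gamma and the terms
#' are combined by log-sum-exp.
#'
#' @param k Observed success count (scalar integer).
#' @param N Population size.
#' @param K Successes in the population.
#' @param n Sample (top-list) size.
#' @return Natural-log p-value, a scalar `<= 0`.
#' @export
log_hypergeom_tail <- function(k, N, K, n) {
  if (K > N || n > N) stop("require K <= N and n <= N")
  if (k < 0 || k > min(n, K)) {
    if (k > min(n, K)) return(-Inf)
    stop("require 0 <= k")
  }
  if (k == 0L) return(0)
  i <- k:min(n, K)
  log_terms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(logsumexp(log_terms), 0)
}

#' Enrichment profile of a database over its score thresholds
#'
#' Sorts a database's interactions by normalized score (descending) and runs
#' one upper-tail hypergeometric test per distinct score value: the top list
#' is every interaction scoring at or above the threshold (ties enter
#' together), the population is the universe, and successes are
#' experimentally validated pairs.
#'
#' @param db A normalized [scored_db()] whose pairs are contained in
#'   `universe`.
#' @param gold A [gold_standard()].
#' @param universe A [build_universe()] result.
#' @return A data.frame with one row per distinct threshold: `threshold`,
#'   `n` (top-list size), `k` (validated in the top list), `log_p`.
#' @export
enrichment_profile <- function(db, gold, universe) {
  stopifnot(inherits(db, "scored_db"))
  ns <- db$interactions$norm_score
  if (anyNA(ns)) stop("database '", db$name, "' must be normalized first")
  if (!nrow(db$interactions)) stop("empty database")
  keys <- db_keys(db)
  if (!all(keys %in% universe$keys)) {
    stop("database '", db$name, "' contains pairs outside the universe")
  }
  ord <- order(-ns, method = "radix")
  s <- ns[ord]
  val <- keys[ord] %in% gold$keys
  # last index of every distinct-score group = candidate threshold
  cut_idx <- cumsum(rle(s)$lengths)
  n_at <- cut_idx
  k_at <- cumsum(val)[cut_idx]
  N <- length(universe$keys)
  K <- universe$validated_count
  log_p <- mapply(log_hypergeom_tail, k = k_at, n = n_at,
                  MoreArgs = list(N = N, K = K))
  data.frame(threshold = s[cut_idx], n = n_at, k = k_at, log_p = log_p)
}

#' Best enrichment of a database (its reliability statistic)
#'
#' Picks the threshold with the lowest hypergeometric p-value along the
#' [enrichment_profile()] sweep — the most enriched score cut — and
#' summarizes it as a z-score, the normal quantile of the minimal p-value
#' evaluated in log space (so p-values as small as `e^-4000` still yield a
#' finite z). More negative z means stronger enrichment in validated
#' interactions. No multiple-testing correction is applied across the sweep;
#' the raw minimum is deliberately optimistic and is used for *ranking*
#' databases, not as a calibrated p-value. Ties in the minimum are resolved
#' toward the smallest top list (the most conservative selected set).
#'
#' @inheritParams enrichment_profile
#' @return A one-row data.frame of class `reliability_result`: `db_name`,
#'   `z_score`, `best_n`, `best_k`, `log_p`, `db_size`, `db_validated`,
#'   `validated_fraction`, `pct_drawn`.
#' @export
best_enrichment <- function(db, gold, universe) {
  prof <- enrichment_profile(db, gold, universe)
  best <- which.min(prof$log_p)  # profile is ordered by increasing n:
                                 # first minimum = smallest top list
  m <- nrow(db$interactions)
  n_val <- sum(db_keys(db) %in% gold$keys)
  res <- data.frame(
    db_name = db$name,
    z_score = stats::qnorm(prof$log_p[best], log.p = TRUE),
    best_n = prof$n[best],
    best_k = prof$k[best],
    log_p = prof$log_p[best],
    db_size = m,
    db_validated = n_val,
    validated_fraction = n_val / m,
    pct_drawn = 100 * prof$n[best] / m,
    stringsAsFactors = FALSE
  )
  class(res) <- c("reliability_result", class(res))
  res
}

#' Rank databases by reliability
#'
#' Orders reliability results by ascending z-score (most negative, i.e. most
#' enriched, first); ties are broken alphabetically by database name.
#'
#' @param results A list of [best_enrichment()] results, or a data.frame of
#'   stacked results.
#' @return A data.frame sorted by reliability.
#' @export
rank_databases <- function(results) {
  if (is.data.frame(results)) tab <- results
  else {
    if (!length(results)) stop("no reliability results to rank")
    tab <- do.call(rbind, results)
  }
  tab <- tab[order(tab$z_score, tab$db_name, method = "radix"), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Reliability table for an ensemble
#'
#' Convenience wrapper: [best_enrichment()] for every database (and
#' optionally for combined score sets), ranked by [rank_databases()].
#'
#' @param dbs List of normalized [scored_db()].
#' @inheritParams enrichment_profile
#' @return Ranked reliability data.frame.
#' @export
reliability_table <- function(dbs, gold, universe) {
  rank_databases(lapply(dbs, best_enrichment, gold = gold,
                        universe = universe))
}
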