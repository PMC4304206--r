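#' Build the prediction universe
#'
#' The universe E is the population of the hypergeometric reliability test:
#' every (miRNA, gene) pair predicted by at least one database, with any
#' score. Gold-standard pairs never predicted by any database are *not* part
#' of the universe — in evaluation they count as false negatives at every
#' threshold.
#'
#' @param dbs Non-empty list of gene-level [scored_db()] objects.
#' @param gold A [gold_standard()].
#' @return An object of class `universe` with elements `pairs` (data.frame),
#'   `keys`, `validated` (logical per pair), `validated_count` and
#'   `n_gold_outside` (validated pairs not predicted by any database).
#' @export
build_universe <- function(dbs, gold) {
  if (!length(dbs)) stop("at least one database is required")
  stopifnot(all(vapply(dbs, inherits, TRUE, "scored_db")),
            inherits(gold, "gold_standard"))
  if (any(vapply(dbs, function(d) d$level, "") != "gene")) {
    stop("all databases must be harmonized to gene level before building ",
         "the universe")
  }
  keys <- unique(unlist(lapply(dbs, db_keys), use.names = FALSE))
  keys <- sort(keys, method = "radix")
  parts <- strsplit(keys, "\t", fixed = TRUE)
  pairs <- data.frame(
    mirna_id = vapply(parts, `[`, "", 1L),
    gene_id = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
  validated <- keys %in% gold$keys
  structure(
    list(pairs = pairs, keys = keys, validated = validated,
         validated_count = sum(validated),
         n_gold_outside = sum(!(gold$keys %in% keys))),
    class = "universe"
  )
}

#' @export
print.universe <- function(x, ...) {
  cat("<universe> ", length(x$keys), " predicted pairs, ",
      x$validated_count, " validated (",
      x$n_gold_outside, " validated pair(s) never predicted)\n", sep = "")
  invisible(x)
}

#' Union and intersection baselines
#'
#' The two classical database-integration baselines: the set of pairs
#' predicted by any database (union) or by every database (intersection).
#'
#' @param dbs List of at least two gene-level [scored_db()].
#' @return Character vector of pair keys; use [baseline_scores()] to evaluate
#'   them alongside scored methods.
#' @export
union_baseline <- function(dbs) {
  stopifnot(length(dbs) >= 2L)
  unique(unlist(lapply(dbs, db_keys), use.names = FALSE))
}

#' @rdname union_baseline
#' @export
intersection_baseline <- function(dbs) {
  stopifnot(length(dbs) >= 2L)
  Reduce(intersect, lapply(dbs, db_keys))
}

#' Score a set-valued baseline over the universe
#'
#' Members of the set get score 1, all other universe pairs 0, producing a
#' two-level ranking comparable with WSP/LRS output in ROC and precision
#' curves.
#'
#' @param set_keys Character vector of pair keys (e.g. from
#'   [intersection_baseline()]).
#' @param universe A [build_universe()] result.
#' @param method Label recorded on the result.
#' @return A `combined_scores` object.
#' @export
baseline_scores <- function(set_keys, universe, method = "baseline") {
  s <- as.numeric(universe$keys %in% set_keys)
  combined_scores(method, universe, s)
}

# Shared constructor for combined / baseline score sets over the universe.
combined_scores <- function(method, universe, scores, n_supporting = NULL,
                            extra = list()) {
  stopifnot(length(scores) == length(universe$keys))
  structure(
    c(list(method = method,
           pairs = universe$pairs,
           keys = universe$keys,
           scores = as.numeric(scores),
           n_supporting = n_supporting),
      extra),
    class = "combined_scores"
  )
}

#' @export
print.combined_scores <- function(x, ...) {
  cat("<combined_scores> method ", x$method, ": ", length(x$keys),
      " pairs, score range [", format(min(x$scores), digits = 4), ", ",
      format(max(x$scores), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Write combined scores as canonical TSV
#'
#' @param cs A `combined_scores` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_combined_tsv <- function(cs, path) {
  out <- data.frame(cs$pairs, score = cs$scores,
                    stringsAsFactors = FALSE)
  names(out)[3] <- if (identical(cs$method, "LRS")) "lrs_probability"
                   else paste0(tolower(cs$method), "_score")
  if (!is.null(cs$n_supporting)) out$n_supporting_dbs <- cs$n_supporting
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
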