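#' Construct a scored prediction database
#'
#' A `scored_db` holds the interaction table of one prediction source: one row
#' per (miRNA, gene/transcript) pair with the database's native score and,
#' after normalization, a confidence score in \[0, 1\] where 1 is the highest
#' confidence.
#'
#' @param name Database name (used in reports and combined-score provenance).
#' @param interactions A data.frame with columns `mirna_id`, `gene_id`,
#'   `raw_score` and optionally `norm_score`.
#' @param direction `"higher_is_better"` for scores that grow with confidence,
#'   `"lower_is_better"` for energy-like scores (e.g. predicted binding free
#'   energies) where more negative means more confident.
#' @param level `"gene"` if `gene_id` is already a gene identifier,
#'   `"transcript"` if predictions are transcript-wise and still need
#'   collapsing via [harmonize()].
#' @param dedup How to resolve duplicate (miRNA, gene) rows: `"keep_best"`
#'   retains the most confident raw score (per `direction`); `"error"` refuses.
#' @return An object of class `scored_db`.
#' @export
scored_db <- function(name, interactions,
                      direction = c("higher_is_better", "lower_is_better"),
                      level = c("gene", "transcript"),
                      dedup = c("keep_best", "error")) {
  direction <- match.arg(direction)
  level <- match.arg(level)
  dedup <- match.arg(dedup)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  required <- c("mirna_id", "gene_id", "raw_score")
  missing_cols <- setdiff(required, names(interactions))
  if (length(missing_cols)) {
    stop("interaction table for '", name, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(interactions, stringsAsFactors = FALSE)
  df$mirna_id <- as.character(df$mirna_id)
  df$gene_id <- as.character(df$gene_id)
  df$raw_score <- as.numeric(df$raw_score)
  if (!"norm_score" %in% names(df)) df$norm_score <- NA_real_
  if (nrow(df) == 0L) stop("database '", name, "' is empty")
  if (any(!nzchar(df$mirna_id)) || any(!nzchar(df$gene_id)) ||
      anyNA(df$mirna_id) || anyNA(df$gene_id)) {
    stop("database '", name, "' contains empty or missing identifiers")
  }
  ok <- df$norm_score[!is.na(df$norm_score)]
  if (length(ok) && (any(ok < 0) || any(ok > 1))) {
    stop("norm_score outside [0, 1] in database '", name, "'")
  }
  df <- dedup_pairs(df, direction, name, action = dedup)
  rownames(df) <- NULL
  structure(
    list(name = name, interactions = df, direction = direction, level = level),
    class = "scored_db"
  )
}

# Keep-best deduplication of (mirna, gene) pairs. "Best" is the most
# confident raw score under the database's score direction.
dedup_pairs <- function(df, direction, name, action = "keep_best") {
  key <- pair_key(df$mirna_id, df$gene_id)
  if (!anyDuplicated(key)) return(df)
  if (action == "error") stop("duplicate (miRNA, gene) pairs in '", name, "'")
  conf <- if (direction == "higher_is_better") df$raw_score else -df$raw_score
  ord <- order(key, -conf, method = "radix")
  df <- df[ord, , drop = FALSE]
  key <- key[ord]
  dropped <- sum(duplicated(key))
  df <- df[!duplicated(key), , drop = FALSE]
  msg("mirfuse: '", name, "': collapsed ", dropped,
      " duplicate pair(s), keeping the most confident score")
  df
}

#' @export
print.scored_db <- function(x, ...) {
  cat("<scored_db> ", x$name, ": ", nrow(x$interactions), " interactions (",
      x$level, "-level, ", x$direction, "); normalized: ",
      ifelse(anyNA(x$interactions$norm_score), "no", "yes"), "\n", sep = "")
  invisible(x)
}

#' Number of interactions in a database
#' @param db A `scored_db`.
#' @return Integer row count.
#' @export
db_size <- function(db) nrow(db$interactions)

# internal: pair keys of a database
db_keys <- function(db) pair_key(db$interactions$mirna_id, db$interactions$gene_id)

#' Construct a gold standard of experimentally validated interactions
#'
#' The gold standard is the union of one or more tables of validated
#' (miRNA, gene) pairs; membership is exact set semantics. Per-pair source
#' provenance is retained.
#'
#' @param ... One or more data.frames with columns `mirna_id` and `gene_id`,
#'   or character vectors are not accepted. Each argument may be named; the
#'   name is recorded as the pair's source database.
#' @return An object of class `gold_standard` with elements `pairs`
#'   (data.frame `mirna_id`, `gene_id`), `keys` and `sources` (named list,
#'   key -> character vector of sources).
#' @export
gold_standard <- function(...) {
  tabs <- list(...)
  if (!length(tabs)) stop("at least one validated-interaction table required")
  nm <- names(tabs)
  if (is.null(nm)) nm <- rep("", length(tabs))
  nm[!nzchar(nm)] <- paste0("source", seq_along(tabs))[!nzchar(nm)]
  all_keys <- character(0)
  src <- list()
  rows <- list()
  for (i in seq_along(tabs)) {
    t <- as.data.frame(tabs[[i]], stringsAsFactors = FALSE)
    stopifnot(all(c("mirna_id", "gene_id") %in% names(t)))
    k <- unique(pair_key(as.character(t$mirna_id), as.character(t$gene_id)))
    for (key in k) src[[key]] <- union(src[[key]], nm[i])
    new <- setdiff(k, all_keys)
    all_keys <- c(all_keys, new)
  }
  parts <- strsplit(all_keys, "\t", fixed = TRUE)
  pairs <- data.frame(
    mirna_id = vapply(parts, `[`, "", 1L),
    gene_id = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
  structure(list(pairs = pairs, keys = all_keys, sources = src),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("<gold_standard> ", length(x$keys), " validated pairs from ",
      length(unique(unlist(x$sources))), " source(s)\n", sep = "")
  invisible(x)
}

#' Test gold-standard membership
#' @param gold A `gold_standard`.
#' @param mirna_id,gene_id Character vectors (recycled together).
#' @return Logical vector.
#' @export
is_validated <- function(gold, mirna_id, gene_id) {
  pair_key(mirna_id, gene_id) %in% gold$keys
}
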