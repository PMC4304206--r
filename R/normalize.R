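#' Min-max score normalization
#'
#' Rescales raw scores linearly to \[0, 1\] with 1 the highest confidence:
#' `(raw - min) / (max - min)` for `higher_is_better` databases and one minus
#' that for `lower_is_better` (energy-like) databases, so the most confident
#' interaction always gets exactly 1.
#'
#' If every raw score is identical the database carries no ranking
#' information; all normalized scores are set to 1 and a warning is issued.
#'
#' @param db A [scored_db()].
#' @return The database with `norm_score` filled; `direction` becomes
#'   `"higher_is_better"` since normalized scores are confidence-increasing.
#' @export
normalize_minmax <- function(db) {
  stopifnot(inherits(db, "scored_db"))
  x <- db$interactions$raw_score
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("database '", db$name,
            "' has a single distinct score; all normalized scores set to 1")
    ns <- rep(1, length(x))
  } else {
    ns <- (x - rng[1]) / (rng[2] - rng[1])
    if (db$direction == "lower_is_better") ns <- 1 - ns
  }
  db$interactions$norm_score <- ns
  db$direction <- "higher_is_better"
  db
}

#' Rank / empirical-CDF score normalization
#'
#' Replaces each score by its empirical cumulative fraction in confidence
#' order: interactions are ranked from worst to best confidence and the
#' normalized score is `rank / n`, so the best interaction gets exactly 1 and
#' every score lies in (0, 1]. This removes the effect of densely packed
#' scoring ranges: the normalized values depend only on `n` and the tie
#' pattern, never on the raw score magnitudes.
#'
#' Ties share the maximum rank of their group (the most favorable value),
#' which keeps the transform deterministic and permutation-invariant.
#'
#' @param db A [scored_db()].
#' @return The database with `norm_score` filled and `direction` set to
#'   `"higher_is_better"`.
#' @export
normalize_rank_cdf <- function(db) {
  stopifnot(inherits(db, "scored_db"))
  x <- db$interactions$raw_score
  conf <- if (db$direction == "lower_is_better") -x else x
  r <- rank(conf, ties.method = "max")
  db$interactions$norm_score <- r / length(r)
  db$direction <- "higher_is_better"
  db
}

#' Normalize a list of databases
#'
#' @param dbs List of [scored_db()].
#' @param method `"minmax"` or `"rank_cdf"`.
#' @return List of normalized databases.
#' @export
normalize_all <- function(dbs, method = c("minmax", "rank_cdf")) {
  method <- match.arg(method)
  f <- switch(method, minmax = normalize_minmax, rank_cdf = normalize_rank_cdf)
  lapply(dbs, f)
}
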