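# Evaluation against the gold standard over the prediction universe.
#
# TP at a threshold: predicted at-or-above it and validated. TN: neither
# predicted above threshold nor validated (within the universe — there is no
# catalogue of true non-interactions, so negatives are relative to the
# universe and AUC must be read the same way). Validated pairs never
# predicted by any database have no score: they are false negatives at every
# threshold and are carried through the sweep as items ranked below every
# scored pair.

# Extract (score, label) vectors over the universe from either a
# combined_scores object or a single scored_db. Pairs of the universe not
# covered by a scored_db get -Inf (never predicted at any threshold).
# Gold pairs outside the universe are appended as -Inf positives when
# include_unpredicted_gold is TRUE.
eval_vectors <- function(scores, gold, universe,
                         include_unpredicted_gold = TRUE) {
  if (inherits(scores, "combined_scores")) {
    s <- scores$scores
    stopifnot(length(s) == length(universe$keys))
  } else if (inherits(scores, "scored_db")) {
    ns <- scores$interactions$norm_score
    if (anyNA(ns)) stop("database '", scores$name, "' must be normalized")
    s <- rep(-Inf, length(universe$keys))
    idx <- match(db_keys(scores), universe$keys)
    if (anyNA(idx)) stop("database pairs outside the universe")
    s[idx] <- ns
  } else stop("scores must be a combined_scores or scored_db object")
  lab <- universe$validated
  if (include_unpredicted_gold && universe$n_gold_outside > 0L) {
    s <- c(s, rep(-Inf, universe$n_gold_outside))
    lab <- c(lab, rep(TRUE, universe$n_gold_outside))
  }
  list(score = s, label = lab)
}

# AUC as the Mann-Whitney rank statistic with midranks for ties; equals the
# trapezoidal area under the tie-grouped ROC sweep.
auc_rank <- function(score, label) {
  n_pos <- sum(label)
  n_neg <- sum(!label)
  if (n_pos == 0L || n_neg == 0L) stop("AUC needs both classes present")
  r <- rank(score, ties.method = "average")
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve and AUC over the universe
#'
#' Sweeps the threshold over the distinct scores in decreasing order (tied
#' scores cross together) and records TPR = TP/(TP+FN) against
#' FPR = FP/(FP+TN). The area under the curve is computed by the trapezoidal
#' rule; by construction it equals the Mann-Whitney rank statistic
#' U/(n_pos * n_neg) with midranks for ties.
#'
#' @param scores A `combined_scores` object or a single normalized
#'   [scored_db()] (whose uncovered universe pairs rank below every scored
#'   pair).
#' @param gold A [gold_standard()].
#' @param universe A [build_universe()] result.
#' @param include_unpredicted_gold Count validated pairs outside the
#'   universe as permanent false negatives (default `TRUE`).
#' @return A list of class `roc_curve`: `thresholds`, `fpr`, `tpr`,
#'   `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, gold, universe,
                      include_unpredicted_gold = TRUE) {
  v <- eval_vectors(scores, gold, universe, include_unpredicted_gold)
  n_pos <- sum(v$label)
  n_neg <- sum(!v$label)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs at least one validated and one non-validated pair")
  }
  ord <- order(v$score, decreasing = TRUE)
  s <- v$score[ord]
  lab <- v$label[ord]
  cut_idx <- cumsum(rle(s)$lengths)
  tp <- cumsum(lab)[cut_idx]
  fp <- cut_idx - tp
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, s[cut_idx]), fpr = fpr, tpr = tpr,
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> AUC = ", format(x$auc, digits = 4), " (",
      x$n_pos, " positives, ", x$n_neg, " negatives)\n", sep = "")
  invisible(x)
}

#' Corrected precision curve
#'
#' Sorts the scores in descending order and reports, for each list depth k,
#' the accumulated precision (validated fraction among the top k) minus the
#' precision a random ordering attains in expectation (the universe's
#' validated fraction). The correction makes curves of differently sized
#' score sets comparable: a method performing at random sits at 0. Unlike
#' the ROC curve, this quantity does not involve the true-negative count,
#' which cannot be estimated for target predictions.
#'
#' @inheritParams roc_curve
#' @param max_points Optional cap on the number of emitted points (the curve
#'   is thinned to an evenly spaced subset of depths; the full-resolution
#'   cumulative counts are still used to compute them).
#' @return A list of class `precision_curve`: `k` (depths), `precision`
#'   (uncorrected), `corrected` (precision minus random expectation),
#'   `random_precision`.
#' @export
precision_curve <- function(scores, gold, universe, max_points = NULL) {
  v <- eval_vectors(scores, gold, universe,
                    include_unpredicted_gold = FALSE)
  # only scored (predicted) pairs enter the top-k list
  keep <- is.finite(v$score)
  s <- v$score[keep]
  lab <- v$label[keep]
  ord <- order(s, decreasing = TRUE)
  lab <- lab[ord]
  prec <- cumsum(lab) / seq_along(lab)
  f <- universe$validated_count / length(universe$keys)
  k <- seq_along(prec)
  if (!is.null(max_points) && length(k) > max_points) {
    idx <- unique(round(seq(1L, length(k), length.out = max_points)))
    k <- k[idx]; prec <- prec[idx]
  }
  structure(list(k = k, precision = prec, corrected = prec - f,
                 random_precision = f),
            class = "precision_curve")
}

#' @export
print.precision_curve <- function(x, ...) {
  cat("<precision_curve> ", length(x$k), " depths, random precision ",
      format(x$random_precision, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Evaluation summary for several score sets
#'
#' @param score_sets Named list of `combined_scores` and/or normalized
#'   [scored_db()] objects.
#' @inheritParams roc_curve
#' @return A data.frame: `method`, `auc`, `n_interactions` (scored pairs).
#' @export
evaluation_summary <- function(score_sets, gold, universe,
                               include_unpredicted_gold = TRUE) {
  rows <- lapply(names(score_sets), function(nm) {
    obj <- score_sets[[nm]]
    n_int <- if (inherits(obj, "scored_db")) db_size(obj)
             else length(obj$keys)
    rc <- roc_curve(obj, gold, universe, include_unpredicted_gold)
    data.frame(method = nm, auc = rc$auc, n_interactions = n_int,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write curve points as TSV
#'
#' @param curve A `roc_curve` or `precision_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_tsv <- function(curve, path) {
  df <- if (inherits(curve, "roc_curve")) {
    data.frame(threshold = curve$thresholds, fpr = curve$fpr,
               tpr = curve$tpr)
  } else {
    data.frame(k = curve$k, precision = curve$precision,
               corrected_precision = curve$corrected)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
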