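#' Validated fraction per score bin
#'
#' Divides a database's score-sorted interaction list into `n_bins`
#' equal-count (quantile) bins and computes the fraction of experimentally
#' validated interactions in each. Equal-count binning guarantees no empty
#' bins even under heavily skewed score distributions. Before smoothing, the
#' bins satisfy the exact identity
#' `sum(count * fraction) == total validated pairs in the database`.
#'
#' @param db A normalized [scored_db()].
#' @param gold A [gold_standard()].
#' @param n_bins Number of bins, at least 2 and at most `db_size(db)`.
#' @return A data.frame with one row per bin (in increasing score order):
#'   `midpoint` (mean normalized score in the bin), `lower`, `upper`
#'   (score range), `count`, `validated`, `fraction`.
#' @export
bin_validation_fraction <- function(db, gold, n_bins = 50L) {
  stopifnot(inherits(db, "scored_db"))
  m <- db_size(db)
  if (n_bins < 2L) stop("n_bins must be at least 2")
  if (n_bins > m) {
    stop("n_bins (", n_bins, ") exceeds the database size (", m, ")")
  }
  df <- db$interactions
  if (anyNA(df$norm_score)) stop("database '", db$name, "' must be normalized")
  ord <- order(df$norm_score, df$mirna_id, df$gene_id, method = "radix")
  s <- df$norm_score[ord]
  val <- pair_key(df$mirna_id, df$gene_id)[ord] %in% gold$keys
  bin <- ceiling(seq_len(m) * n_bins / m)
  data.frame(
    midpoint = as.numeric(tapply(s, bin, mean)),
    lower = as.numeric(tapply(s, bin, min)),
    upper = as.numeric(tapply(s, bin, max)),
    count = as.integer(tapply(val, bin, length)),
    validated = as.integer(tapply(val, bin, sum)),
    fraction = as.numeric(tapply(val, bin, mean))
  )
}

#' Fit a calibration curve from binned validation fractions
#'
#' Interpolates the (bin score midpoint, validated fraction) points with a
#' cubic smoothing spline, yielding a smooth map from normalized score to
#' the probability of being experimentally validated. The smoothing
#' parameter defaults to generalized cross-validation. Evaluation clamps the
#' input to the observed midpoint range (no linear extrapolation) and the
#' output to \[0, 1\].
#'
#' With fewer than four distinct midpoints a smoothing spline is not
#' identifiable; the curve falls back to linear interpolation, and with a
#' single distinct midpoint to a constant (step) function, with a message.
#'
#' @param bins A [bin_validation_fraction()] result (>= 2 rows).
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()]; `NULL` selects it by generalized
#'   cross-validation.
#' @param db_name Name recorded on the curve.
#' @return An object of class `calibration_curve`; call it via
#'   [predict_calibration()].
#' @export
fit_calibration <- function(bins, spar = NULL, db_name = "") {
  stopifnot(is.data.frame(bins), nrow(bins) >= 2L)
  x <- bins$midpoint
  y <- bins$fraction
  n_distinct <- length(unique(x))
  if (n_distinct == 1L) {
    msg("mirfuse: calibration for '", db_name,
        "': degenerate identical midpoints; using a constant fit")
    fit <- list(kind = "constant", value = mean(y))
  } else if (n_distinct < 4L) {
    msg("mirfuse: calibration for '", db_name,
        "': too few distinct midpoints for a spline; using linear ",
        "interpolation")
    ag <- stats::aggregate(y, list(x = x), mean)
    fit <- list(kind = "linear",
                fun = stats::approxfun(ag$x, ag[[2L]], rule = 2))
  } else {
    ss <- if (is.null(spar)) {
      stats::smooth.spline(x, y, cv = FALSE)  # GCV
    } else {
      stats::smooth.spline(x, y, spar = spar)
    }
    fit <- list(kind = "spline", fun = function(v) {
      stats::predict(ss, v)$y
    })
  }
  structure(list(db_name = db_name, bins = bins, fit = fit,
                 range = range(x)),
            class = "calibration_curve")
}

#' Evaluate a calibration curve
#'
#' @param curve A [fit_calibration()] result.
#' @param score Numeric vector of normalized scores.
#' @return Calibrated probabilities in \[0, 1\]; inputs outside the fitted
#'   midpoint range are clamped to the nearest boundary before evaluation.
#' @export
predict_calibration <- function(curve, score) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$fit$kind == "constant") {
    return(rep(min(max(curve$fit$value, 0), 1), length(score)))
  }
  x <- pmin(pmax(score, curve$range[1]), curve$range[2])
  pmin(pmax(curve$fit$fun(x), 0), 1)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve> ", x$db_name, ": ", nrow(x$bins), " bins, ",
      x$fit$kind, " fit\n", sep = "")
  invisible(x)
}

# Fit calibration curves for every database, restricted (optionally) to a
# subset of universe pair keys (used by cross-validation to keep held-out
# pairs out of the calibration).
fit_all_calibrations <- function(dbs, gold, n_bins, spar = NULL,
                                 restrict_keys = NULL) {
  curves <- lapply(dbs, function(db) {
    if (!is.null(restrict_keys)) {
      keep <- db_keys(db) %in% restrict_keys
      db$interactions <- db$interactions[keep, , drop = FALSE]
      if (!nrow(db$interactions)) {
        stop("database '", db$name, "' has no interactions in the ",
             "training restriction")
      }
    }
    nb <- min(n_bins, db_size(db))
    if (nb < 2L) stop("database '", db$name, "' too small to bin")
    fit_calibration(bin_validation_fraction(db, gold, nb), spar = spar,
                    db_name = db$name)
  })
  names(curves) <- vapply(dbs, function(d) d$name, "")
  curves
}

#' Design matrix of per-database features for the logistic fusion
#'
#' For every requested pair, the per-database feature is the database's
#' calibrated probability of validation evaluated at the pair's normalized
#' score in that database (or, with `features = "score"`, the normalized
#' score itself). A pair absent from a database gets the missing-value fill
#' (default 0: no evidence), which keeps each cross-term interpretable as
#' "both databases support this pair". Cross-features are the pairwise
#' products of the filled per-database features; databases are ordered by
#' sorted name, so the design matrix is invariant to the input order of
#' `dbs`.
#'
#' @param keys Character vector of pair keys to featurize.
#' @param dbs List of normalized [scored_db()].
#' @param curves Named list of [fit_calibration()] curves (one per database;
#'   ignored when `features = "score"`).
#' @param features `"probability"` (spline-calibrated, default) or
#'   `"score"` (raw normalized score).
#' @param fill Value for pairs absent from a database.
#' @param cross Include pairwise cross-terms?
#' @return Numeric matrix, one row per key; main-effect columns named by
#'   database, cross columns `"A:B"`.
#' @export
probability_features <- function(keys, dbs, curves = NULL,
                                 features = c("probability", "score"),
                                 fill = 0, cross = TRUE) {
  features <- match.arg(features)
  db_names <- sort(vapply(dbs, function(d) d$name, ""))
  dbs <- dbs[match(db_names, vapply(dbs, function(d) d$name, ""))]
  X <- matrix(fill, nrow = length(keys), ncol = length(dbs),
              dimnames = list(NULL, db_names))
  for (j in seq_along(dbs)) {
    db <- dbs[[j]]
    hit <- match(db_keys(db), keys)
    in_req <- !is.na(hit)
    sc <- db$interactions$norm_score[in_req]
    v <- if (features == "probability") {
      curve <- curves[[db$name]]
      if (is.null(curve)) stop("no calibration curve for '", db$name, "'")
      predict_calibration(curve, sc)
    } else sc
    X[hit[in_req], j] <- v
  }
  if (cross && length(dbs) >= 2L) {
    cc <- utils::combn(db_names, 2L)
    XC <- matrix(0, nrow = length(keys), ncol = ncol(cc),
                 dimnames = list(NULL, paste(cc[1L, ], cc[2L, ], sep = ":")))
    for (j in seq_len(ncol(cc))) {
      XC[, j] <- X[, cc[1L, j]] * X[, cc[2L, j]]
    }
    X <- cbind(X, XC)
  }
  X
}

#' LRS configuration
#'
#' @param n_bins Bins per database for the calibration step.
#' @param spar Spline smoothing parameter (`NULL` = generalized
#'   cross-validation).
#' @param features Design-matrix features: calibrated `"probability"`
#'   (default) or raw normalized `"score"`.
#' @param penalty `"none"` for the maximum-likelihood fit (default),
#'   `"ridge"` or `"lasso"` for a glmnet fit with internal cross-validation.
#' @param fill Missing-database feature fill.
#' @param cross Include pairwise cross-terms.
#' @return A list of class `lrs_config`.
#' @export
lrs_config <- function(n_bins = 50L, spar = NULL,
                       features = c("probability", "score"),
                       penalty = c("none", "ridge", "lasso"),
                       fill = 0, cross = TRUE) {
  structure(list(n_bins = as.integer(n_bins), spar = spar,
                 features = match.arg(features),
                 penalty = match.arg(penalty), fill = fill,
                 cross = isTRUE(cross)),
            class = "lrs_config")
}

#' Fit the logistic-regression score-fusion model (LRS)
#'
#' Re-scores each interaction in each database as its calibrated probability
#' of being experimentally validated ([bin_validation_fraction()] +
#' [fit_calibration()]), then fits a logistic regression of the validation
#' label on the per-database probabilities and their pairwise cross-terms
#' (which absorb redundancy between databases) over the whole universe.
#'
#' The default fit is unpenalized maximum likelihood via [stats::glm()]. If
#' the fit separates perfectly (fitted probabilities numerically 0 or 1),
#' the model switches to a ridge fit with internal cross-validation
#' ([glmnet::cv.glmnet()]) and reports it.
#'
#' @param dbs List of normalized gene-level [scored_db()].
#' @param gold A [gold_standard()].
#' @param universe A [build_universe()] result; must contain both validated
#'   and non-validated pairs.
#' @param config An [lrs_config()].
#' @return An object of class `lrs_model`: `intercept`, `coefficients`
#'   (named, mains then cross-terms), `curves`, `feature_spec`, `penalty`,
#'   `converged`.
#' @export
fit_lrs <- function(dbs, gold, universe, config = lrs_config()) {
  stopifnot(inherits(config, "lrs_config"))
  label <- as.integer(universe$validated)
  if (all(label == 1L) || all(label == 0L)) {
    stop("the universe must contain both validated and non-validated pairs")
  }
  curves <- if (config$features == "probability") {
    fit_all_calibrations(dbs, gold, config$n_bins, config$spar)
  } else NULL
  X <- probability_features(universe$keys, dbs, curves,
                            features = config$features,
                            fill = config$fill, cross = config$cross)
  fit_lrs_glm(X, label, curves, config)
}

# core fitting on a prepared design matrix (shared with cross-validation)
fit_lrs_glm <- function(X, label, curves, config) {
  feature_spec <- list(db_names = colnames(X)[!grepl(":", colnames(X),
                                                     fixed = TRUE)],
                       features = config$features, fill = config$fill,
                       cross = config$cross, columns = colnames(X))
  penalty <- config$penalty
  if (penalty == "none") {
    Xi <- cbind(`(Intercept)` = 1, X)
    separated <- FALSE
    fit <- withCallingHandlers(
      stats::glm.fit(Xi, label, family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-12,
                                                  maxit = 200)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) {
          separated <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    if (!separated) {
      cf <- stats::coef(fit)
      return(structure(list(intercept = unname(cf[1L]),
                            coefficients = cf[-1L],
                            curves = curves, feature_spec = feature_spec,
                            penalty = "none",
                            converged = fit$converged),
                       class = "lrs_model"))
    }
    msg("mirfuse: LRS fit separated perfectly; switching to a ridge fit")
    penalty <- "ridge"
  }
  alpha <- if (penalty == "ridge") 0 else 1
  cvfit <- glmnet::cv.glmnet(X, label, family = "binomial", alpha = alpha,
                             nfolds = 5L)
  cf <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
  names(cf) <- rownames(stats::coef(cvfit, s = "lambda.min"))
  structure(list(intercept = cf[[1L]],
                 coefficients = stats::setNames(cf[-1L], colnames(X)),
                 curves = curves, feature_spec = feature_spec,
                 penalty = penalty, converged = TRUE),
            class = "lrs_model")
}

#' @export
print.lrs_model <- function(x, ...) {
  cat("<lrs_model> ", length(x$feature_spec$db_names), " databases, ",
      length(x$coefficients), " coefficients (", x$penalty, " fit)\n",
      sep = "")
  invisible(x)
}

#' Predict validation probabilities from a fitted LRS model
#'
#' @param object An [fit_lrs()] model.
#' @param keys Pair keys to score.
#' @param dbs The databases (normalized) supplying the scores.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.lrs_model <- function(object, keys, dbs, ...) {
  config_like <- list(features = object$feature_spec$features,
                      fill = object$feature_spec$fill,
                      cross = object$feature_spec$cross)
  X <- probability_features(keys, dbs, object$curves,
                            features = config_like$features,
                            fill = config_like$fill,
                            cross = config_like$cross)
  X <- X[, names(object$coefficients), drop = FALSE]
  inv_logit(object$intercept + drop(X %*% object$coefficients))
}

#' Combine databases by logistic-regression scoring (LRS)
#'
#' Scores every universe pair with its model-predicted probability of being
#' experimentally validated: the higher the probability, the more reliable
#' the interaction.
#'
#' @inheritParams fit_lrs
#' @param model An already fitted [fit_lrs()] model, or `NULL` to fit one.
#' @return A `combined_scores` object (method `"LRS"`) with the model
#'   attached as `model`.
#' @export
lrs_combine <- function(dbs, gold, universe, model = NULL,
                        config = lrs_config()) {
  if (is.null(model)) model <- fit_lrs(dbs, gold, universe, config)
  p <- predict(model, universe$keys, dbs)
  combined_scores("LRS", universe, p, extra = list(model = model))
}

#' Cross-validated AUC of the LRS model
#'
#' Stratified pair-level k-fold cross-validation: within each fold the
#' calibration curves *and* the logistic model are refit on the training
#' pairs only, and the ROC AUC is computed on the held-out pairs. Comparing
#' the mean held-out AUC with the full-data AUC quantifies the optimism of
#' fitting and evaluating on the same gold standard.
#'
#' @inheritParams fit_lrs
#' @param folds Number of folds (>= 2, at most the positive-class count).
#' @param seed Integer seed for the fold assignment.
#' @return A list: `fold_auc` (numeric vector), `mean_auc`, `full_auc`.
#' @export
cross_validated_auc <- function(dbs, gold, universe, folds = 5L, seed = 1L,
                                config = lrs_config()) {
  if (folds < 2L) stop("folds must be at least 2")
  label <- as.integer(universe$validated)
  n_pos <- sum(label == 1L)
  n_neg <- sum(label == 0L)
  if (folds > min(n_pos, n_neg)) {
    stop("too many folds for ", n_pos, " positive / ", n_neg,
         " negative pairs; use fewer folds")
  }
  set.seed(seed)
  fold <- integer(length(label))
  fold[label == 1L] <- sample(rep_len(seq_len(folds), n_pos))
  fold[label == 0L] <- sample(rep_len(seq_len(folds), n_neg))
  fold_auc <- vapply(seq_len(folds), function(f) {
    train_keys <- universe$keys[fold != f]
    test_idx <- fold == f
    curves <- if (config$features == "probability") {
      fit_all_calibrations(dbs, gold, config$n_bins, config$spar,
                           restrict_keys = train_keys)
    } else NULL
    Xtr <- probability_features(train_keys, dbs, curves,
                                features = config$features,
                                fill = config$fill, cross = config$cross)
    m <- fit_lrs_glm(Xtr, label[fold != f], curves, config)
    if (!sum(label[test_idx])) stop("a fold has no validated pairs; ",
                                    "use fewer folds")
    p <- predict(m, universe$keys[test_idx], dbs)
    auc_rank(p, label[test_idx] == 1L)
  }, numeric(1))
  full <- lrs_combine(dbs, gold, universe, config = config)
  list(fold_auc = fold_auc, mean_auc = mean(fold_auc),
       full_auc = auc_rank(full$scores, label == 1L))
}

#' Serialize / restore an LRS model as plain text
#'
#' Writes the coefficients and feature specification as a key-value text
#' file that round-trips exactly (full double precision via `format(...,
#' digits = 17)`). Calibration curves are not serialized; supply them when
#' predicting from a restored model, or use `features = "score"` models
#' which need none.
#'
#' @param model An `lrs_model`.
#' @param path Output path.
#' @return `path` invisibly; `read_lrs_model` returns an `lrs_model`
#'   (without curves).
#' @export
write_lrs_model <- function(model, path) {
  lines <- c(
    paste0("features\t", model$feature_spec$features),
    paste0("fill\t", format(model$feature_spec$fill, digits = 17)),
    paste0("cross\t", model$feature_spec$cross),
    paste0("penalty\t", model$penalty),
    paste0("db_names\t", paste(model$feature_spec$db_names, collapse = ",")),
    paste0("intercept\t", format(model$intercept, digits = 17)),
    vapply(names(model$coefficients), function(nm) {
      paste0("coef:", nm, "\t", format(model$coefficients[[nm]], digits = 17))
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_lrs_model
#' @export
read_lrs_model <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  get1 <- function(k) vals[match(k, keys)]
  is_coef <- startsWith(keys, "coef:")
  cf <- stats::setNames(as.numeric(vals[is_coef]),
                        sub("^coef:", "", keys[is_coef]))
  db_names <- strsplit(get1("db_names"), ",", fixed = TRUE)[[1L]]
  structure(list(
    intercept = as.numeric(get1("intercept")),
    coefficients = cf,
    curves = NULL,
    feature_spec = list(db_names = db_names, features = get1("features"),
                        fill = as.numeric(get1("fill")),
                        cross = as.logical(get1("cross")),
                        columns = names(cf)),
    penalty = get1("penalty"), converged = TRUE
  ), class = "lrs_model")
}
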