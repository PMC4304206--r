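#' Specify one synthetic prediction database
#'
#' Scores are drawn from truth-conditioned Beta families: interactions that
#' are truly regulatory get scores from `Beta(beta_true)`, spurious ones from
#' `Beta(beta_false)`. This family is chosen because the probability that a
#' true pair outscores a false pair — the database's expected AUC — is
#' available analytically ([expected_auc()]), giving the whole evaluation
#' stack a closed-form oracle. The convenience parameter `auc` sets
#' `beta_true = c(a, 1)` against uniform false scores with `a = auc/(1-auc)`,
#' for which the expected AUC is exactly `a/(a+1) = auc`.
#'
#' @param name Database name.
#' @param n_true Number of truly regulatory pairs the database predicts
#'   (sampled from the ensemble's true-pair set).
#' @param n_false Number of spurious predictions.
#' @param auc Target expected AUC in (0.5, 1); ignored when `beta_true` is
#'   given explicitly. `auc = 0.5` (or `beta_true = beta_false`) yields a
#'   pure-noise database.
#' @param beta_true,beta_false Length-2 shape parameters.
#' @param direction Score direction the database *reports*; with
#'   `"lower_is_better"` the emitted raw score is the negated draw
#'   (energy-like convention).
#' @return A list of class `synthetic_db_spec`.
#' @export
synthetic_db <- function(name, n_true, n_false, auc = NULL,
                         beta_true = NULL, beta_false = c(1, 1),
                         direction = c("higher_is_better",
                                       "lower_is_better")) {
  direction <- match.arg(direction)
  if (is.null(beta_true)) {
    if (is.null(auc)) stop("give either auc or beta_true")
    stopifnot(auc >= 0.5, auc < 1)
    beta_true <- c(auc / (1 - auc), 1)
  }
  structure(list(name = name, n_true = as.integer(n_true),
                 n_false = as.integer(n_false),
                 beta_true = as.numeric(beta_true),
                 beta_false = as.numeric(beta_false),
                 direction = direction),
            class = "synthetic_db_spec")
}

#' Specify a synthetic prediction ensemble
#'
#' Defines the interaction grid (miRNAs x genes), the set of truly
#' regulatory pairs, the experimental validation coverage (which fraction of
#' true pairs the gold standard actually confirms — real validation
#' databases are far from exhaustive), and the per-database score models.
#'
#' @param n_mirnas,n_genes Grid dimensions.
#' @param n_true_pairs Number of truly regulatory (miRNA, gene) pairs.
#' @param databases List of [synthetic_db()] specs.
#' @param validation_coverage Probability that a true pair is experimentally
#'   validated (enters the gold standard). Default 0.6.
#' @param seed Master seed; per-database substreams are derived from it, so
#'   the whole ensemble is reproducible from `seed` alone.
#' @return A list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_mirnas, n_genes, n_true_pairs, databases,
                          validation_coverage = 0.6, seed = 1L) {
  stopifnot(validation_coverage >= 0, validation_coverage <= 1,
            length(databases) >= 1L,
            all(vapply(databases, inherits, TRUE, "synthetic_db_spec")))
  n_cells <- as.numeric(n_mirnas) * as.numeric(n_genes)
  if (n_true_pairs > n_cells) {
    stop("more true pairs than grid cells (", n_true_pairs, " > ",
         n_cells, ")")
  }
  for (d in databases) {
    if (d$n_true > n_true_pairs) {
      stop("database '", d$name, "' asks for more true pairs than exist")
    }
    if (d$n_false > n_cells - n_true_pairs) {
      stop("database '", d$name, "' asks for more false pairs than exist")
    }
  }
  structure(list(n_mirnas = as.integer(n_mirnas),
                 n_genes = as.integer(n_genes),
                 n_true_pairs = as.integer(n_true_pairs),
                 databases = databases,
                 validation_coverage = validation_coverage,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

# cell index -> (mirna, gene) ids
cell_ids <- function(cells, n_genes) {
  mi <- (cells - 1L) %/% n_genes + 1L
  gi <- (cells - 1L) %% n_genes + 1L
  list(mirna = sprintf("mir-%04d", mi), gene = sprintf("G%05d", gi))
}

#' Generate a synthetic prediction ensemble with known ground truth
#'
#' Draws the true-pair set, the gold standard (each true pair validated
#' independently with probability `validation_coverage`), and one scored
#' database per spec: `n_true` pairs sampled from the true set and `n_false`
#' spurious pairs sampled from the rest of the grid, with raw scores drawn
#' from the spec's truth-conditioned Beta families. Output is fully
#' determined by `spec$seed`.
#'
#' @param spec An [ensemble_spec()].
#' @return A list: `dbs` (list of gene-level [scored_db()], raw scores
#'   only), `gold` (a [gold_standard()]), `truth` (character vector of all
#'   true pair keys), `spec`.
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  n_cells <- as.numeric(spec$n_mirnas) * as.numeric(spec$n_genes)
  set.seed(spec$seed)
  true_cells <- sort(sample.int(n_cells, spec$n_true_pairs))
  tid <- cell_ids(true_cells, spec$n_genes)
  truth_keys <- pair_key(tid$mirna, tid$gene)
  validated <- stats::runif(spec$n_true_pairs) < spec$validation_coverage
  if (!any(validated)) stop("no true pair was validated; increase ",
                            "validation_coverage or n_true_pairs")
  gold <- gold_standard(
    `synthetic-validation` = data.frame(mirna_id = tid$mirna[validated],
                                        gene_id = tid$gene[validated],
                                        stringsAsFactors = FALSE)
  )
  dbs <- lapply(seq_along(spec$databases), function(i) {
    d <- spec$databases[[i]]
    set.seed(derive_seed(spec$seed, i))
    tsel <- sample.int(spec$n_true_pairs, d$n_true)
    # rejection-sample false cells from the grid complement
    fcells <- integer(0)
    while (length(fcells) < d$n_false) {
      cand <- sample.int(n_cells, d$n_false - length(fcells) + 100L,
                         replace = FALSE)
      cand <- setdiff(cand, c(true_cells, fcells))
      fcells <- c(fcells, cand)
    }
    fcells <- fcells[seq_len(d$n_false)]
    fid <- cell_ids(fcells, spec$n_genes)
    s_true <- stats::rbeta(d$n_true, d$beta_true[1], d$beta_true[2])
    s_false <- stats::rbeta(d$n_false, d$beta_false[1], d$beta_false[2])
    raw <- c(s_true, s_false)
    if (d$direction == "lower_is_better") raw <- -raw
    scored_db(
      name = d$name,
      interactions = data.frame(
        mirna_id = c(tid$mirna[tsel], fid$mirna),
        gene_id = c(tid$gene[tsel], fid$gene),
        raw_score = raw,
        stringsAsFactors = FALSE
      ),
      direction = d$direction, level = "gene"
    )
  })
  names(dbs) <- vapply(spec$databases, `[[`, "", "name")
  list(dbs = dbs, gold = gold, truth = truth_keys, spec = spec)
}

#' Analytic expected AUC of a synthetic database
#'
#' The probability that a true pair outscores a false pair,
#' `P(S_T > S_F)` with `S_T ~ Beta(beta_true)` and `S_F ~ Beta(beta_false)`,
#' computed as the integral of the false-score CDF against the true-score
#' density by adaptive quadrature. Identical families give exactly 0.5 by
#' symmetry.
#'
#' @param spec An [ensemble_spec()] or a single [synthetic_db()].
#' @param db_index Which database, when `spec` is an ensemble spec.
#' @return Expected AUC in \[0, 1\].
#' @export
expected_auc <- function(spec, db_index = 1L) {
  d <- if (inherits(spec, "ensemble_spec")) spec$databases[[db_index]]
       else spec
  stopifnot(inherits(d, "synthetic_db_spec"))
  if (identical(d$beta_true, d$beta_false)) return(0.5)
  f <- function(x) stats::pbeta(x, d$beta_false[1], d$beta_false[2]) *
    stats::dbeta(x, d$beta_true[1], d$beta_true[2])
  stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
}

#' Write a generated ensemble as canonical TSVs plus a manifest
#'
#' @param ens A [generate_ensemble()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_ensemble <- function(ens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (db in ens$dbs) {
    write_canonical_tsv(db, file.path(dir, paste0(db$name, ".tsv")))
  }
  utils::write.table(ens$gold$pairs, file.path(dir, "gold_standard.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sp <- ens$spec
  manifest <- c(
    sprintf("n_mirnas: %d", sp$n_mirnas),
    sprintf("n_genes: %d", sp$n_genes),
    sprintf("n_true_pairs: %d", sp$n_true_pairs),
    sprintf("validation_coverage: %g", sp$validation_coverage),
    sprintf("seed: %d", sp$seed),
    "databases:",
    unlist(lapply(sp$databases, function(d) {
      sprintf("  - {name: %s, n_true: %d, n_false: %d, beta_true: [%g, %g], beta_false: [%g, %g], direction: %s}",
              d$name, d$n_true, d$n_false, d$beta_true[1], d$beta_true[2],
              d$beta_false[1], d$beta_false[2], d$direction)
    }))
  )
  writeLines(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
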