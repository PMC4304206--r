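#' Load a run configuration
#'
#' A run is fully described by one declarative YAML file: database inputs
#' (path, column mapping, direction, level), dictionary paths, method
#' parameters (normalization, bins, spline smoothing, penalty, folds, seed)
#' and the output directory. Command-line flags override config values.
#'
#' @param path YAML file, or a named list already in config shape.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(normalization = "minmax", n_bins = 50L, spar = NULL,
                   penalty = "none", folds = 5L, seed = 1L,
                   output_dir = ".")
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  structure(cfg, class = "run_config")
}

# Load + harmonize + normalize the configured databases and gold standard.
load_inputs <- function(config) {
  mirna_aliases <- if (!is.null(config$mirna_alias_path)) {
    read_mirna_aliases(config$mirna_alias_path)
  }
  gene_map <- if (!is.null(config$gene_map_path)) {
    read_gene_map(config$gene_map_path)
  }
  dbs <- lapply(config$databases, function(d) {
    db <- read_interaction_table(
      d$path, name = d$name %||% NULL,
      columns = unlist(d$columns %||% c(mirna = "mirna_id", gene = "gene_id",
                                        score = "raw_score")),
      direction = d$direction %||% "higher_is_better",
      level = d$level %||% "gene",
      sep = d$sep %||% "\t"
    )
    harmonize(db, mirna_aliases, gene_map)
  })
  gold_tabs <- lapply(config$gold_standards, function(g) {
    read_validated_table(g$path,
                         columns = unlist(g$columns %||%
                                            c(mirna = "mirna_id",
                                              gene = "gene_id")),
                         sep = g$sep %||% "\t")
  })
  names(gold_tabs) <- vapply(config$gold_standards,
                             function(g) g$name %||% basename(g$path), "")
  gold <- do.call(gold_standard, gold_tabs)
  dbs <- normalize_all(dbs, config$normalization)
  list(dbs = dbs, gold = gold, universe = build_universe(dbs, gold))
}

#' Run a pipeline command
#'
#' The engine behind the `mirfuse` command-line script. Every command writes
#' its artifacts as TSV into `config$output_dir` and returns them invisibly;
#' given the same config, inputs and seed, outputs are byte-identical.
#'
#' @param command One of `"simulate"`, `"normalize"`, `"reliability"`,
#'   `"combine"`, `"evaluate"`, `"crossval"`.
#' @param config A [read_run_config()] result (or a list coercible to one).
#' @param method For `"combine"`: `"wsp"`, `"lrs"`, `"union"` or
#'   `"intersection"`.
#' @return A list of produced artifact paths, invisibly.
#' @export
run_pipeline <- function(command = c("simulate", "normalize", "reliability",
                                     "combine", "evaluate", "crossval"),
                         config, method = "wsp") {
  command <- match.arg(command)
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)

  if (command == "simulate") {
    sim <- config$simulate
    dbs <- lapply(sim$databases, function(d) {
      synthetic_db(d$name, d$n_true, d$n_false, auc = d$auc,
                   beta_true = d$beta_true, beta_false = d$beta_false %||%
                     c(1, 1),
                   direction = d$direction %||% "higher_is_better")
    })
    spec <- ensemble_spec(sim$n_mirnas, sim$n_genes, sim$n_true_pairs, dbs,
                          validation_coverage = sim$validation_coverage %||%
                            0.6,
                          seed = config$seed)
    ens <- generate_ensemble(spec)
    write_ensemble(ens, out)
    return(invisible(list(dir = out)))
  }

  inp <- load_inputs(config)

  if (command == "normalize") {
    for (db in inp$dbs) {
      p <- file.path(out, paste0(db$name, ".normalized.tsv"))
      write_canonical_tsv(db, p)
      written <- c(written, p)
    }
  } else if (command == "reliability") {
    tab <- reliability_table(inp$dbs, inp$gold, inp$universe)
    p <- file.path(out, "reliability.tsv")
    utils::write.table(
      tab[, c("db_name", "z_score", "best_n", "db_size", "db_validated",
              "validated_fraction", "pct_drawn")],
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- p
  } else if (command == "combine") {
    cs <- switch(method,
      wsp = wsp_combine(inp$dbs, inp$gold, inp$universe),
      lrs = lrs_combine(inp$dbs, inp$gold, inp$universe,
                        config = lrs_config(n_bins = config$n_bins,
                                            spar = config$spar,
                                            penalty = config$penalty)),
      union = baseline_scores(union_baseline(inp$dbs), inp$universe,
                              "union"),
      intersection = baseline_scores(intersection_baseline(inp$dbs),
                                     inp$universe, "intersection"),
      stop("unknown combine method: ", method)
    )
    p <- file.path(out, paste0("combined_", method, ".tsv"))
    write_combined_tsv(cs, p)
    written <- p
  } else if (command == "evaluate") {
    sets <- c(
      stats::setNames(inp$dbs, vapply(inp$dbs, function(d) d$name, "")),
      list(WSP = wsp_combine(inp$dbs, inp$gold, inp$universe),
           LRS = lrs_combine(inp$dbs, inp$gold, inp$universe,
                             config = lrs_config(n_bins = config$n_bins,
                                                 spar = config$spar,
                                                 penalty = config$penalty)))
    )
    if (length(inp$dbs) >= 2L) {
      sets$union <- baseline_scores(union_baseline(inp$dbs), inp$universe,
                                    "union")
      sets$intersection <- baseline_scores(intersection_baseline(inp$dbs),
                                           inp$universe, "intersection")
    }
    summ <- evaluation_summary(sets, inp$gold, inp$universe)
    p <- file.path(out, "summary.tsv")
    utils::write.table(summ, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- p
    for (nm in names(sets)) {
      rp <- file.path(out, paste0("roc_", nm, ".tsv"))
      write_curve_tsv(roc_curve(sets[[nm]], inp$gold, inp$universe), rp)
      pp <- file.path(out, paste0("precision_", nm, ".tsv"))
      write_curve_tsv(precision_curve(sets[[nm]], inp$gold, inp$universe,
                                      max_points = 500L), pp)
      written <- c(written, rp, pp)
    }
  } else if (command == "crossval") {
    cv <- cross_validated_auc(inp$dbs, inp$gold, inp$universe,
                              folds = config$folds, seed = config$seed,
                              config = lrs_config(n_bins = config$n_bins,
                                                  spar = config$spar,
                                                  penalty = config$penalty))
    p <- file.path(out, "crossval.tsv")
    utils::write.table(
      data.frame(fold = c(seq_along(cv$fold_auc), NA, NA),
                 metric = c(rep("fold_auc", length(cv$fold_auc)),
                            "mean_cv_auc", "full_data_auc"),
                 auc = c(cv$fold_auc, cv$mean_auc, cv$full_auc)),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- p
  }
  invisible(list(files = written))
}
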