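#' Read a delimited interaction table into a scored database
#'
#' Parses a TSV/CSV prediction table (gzip transparently accepted) into a
#' [scored_db()]. Column roles are configurable so heterogeneous database
#' dumps can be ingested without reshaping. Rows whose score does not parse
#' as a number are dropped and counted in a message.
#'
#' @param path Path to a delimited file; `.gz` is handled by
#'   [base::gzfile()] via `read.delim`.
#' @param name Database name; defaults to the file name without extension.
#' @param columns Named character vector mapping the roles `mirna`, `gene`,
#'   `score` to column names in the file.
#' @param direction,level,dedup Passed to [scored_db()].
#' @param sep Field separator; `"\t"` (default) or `","`.
#' @return A `scored_db` with raw scores only (`norm_score` unset).
#' @export
read_interaction_table <- function(path,
                                   name = sub("\\.(tsv|csv|txt)(\\.gz)?$", "",
                                              basename(path)),
                                   columns = c(mirna = "mirna", gene = "gene",
                                               score = "score"),
                                   direction = "higher_is_better",
                                   level = "gene",
                                   dedup = "keep_best",
                                   sep = "\t") {
  if (!file.exists(path)) stop("input file not found: ", path)
  stopifnot(all(c("mirna", "gene", "score") %in% names(columns)))
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE)
  for (role in c("mirna", "gene", "score")) {
    if (!columns[[role]] %in% names(raw)) {
      stop("column '", columns[[role]], "' (role: ", role,
           ") not present in ", path)
    }
  }
  if (nrow(raw) == 0L) stop("interaction table is empty: ", path)
  score <- suppressWarnings(as.numeric(raw[[columns[["score"]]]]))
  bad <- is.na(score)
  if (any(bad)) {
    msg("mirfuse: '", name, "': dropped ", sum(bad),
        " row(s) with unparseable scores")
  }
  if (all(bad)) stop("no parseable scores in ", path)
  scored_db(
    name = name,
    interactions = data.frame(
      mirna_id = raw[[columns[["mirna"]]]][!bad],
      gene_id = raw[[columns[["gene"]]]][!bad],
      raw_score = score[!bad],
      stringsAsFactors = FALSE
    ),
    direction = direction, level = level, dedup = dedup
  )
}

#' Read a gold-standard table of validated interactions
#'
#' @inheritParams read_interaction_table
#' @param columns Named character vector mapping roles `mirna`, `gene` to
#'   column names.
#' @return A data.frame with columns `mirna_id`, `gene_id`, suitable for
#'   [gold_standard()].
#' @export
read_validated_table <- function(path,
                                 columns = c(mirna = "mirna", gene = "gene"),
                                 sep = "\t") {
  if (!file.exists(path)) stop("input file not found: ", path)
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE)
  stopifnot(all(columns[c("mirna", "gene")] %in% names(raw)))
  data.frame(mirna_id = raw[[columns[["mirna"]]]],
             gene_id = raw[[columns[["gene"]]]],
             stringsAsFactors = FALSE)
}

#' Build an alias map from synonym/canonical columns
#'
#' An alias map sends synonyms to canonical identifiers. Canonical ids always
#' map to themselves, so applying a map twice is a no-op.
#'
#' @param canonical Character vector of canonical ids.
#' @param synonym Character vector of synonyms, same length.
#' @return A named character vector (class `alias_map`): names are synonyms,
#'   values canonical ids.
#' @export
alias_map <- function(canonical = character(0), synonym = character(0)) {
  stopifnot(length(canonical) == length(synonym))
  m <- c(stats::setNames(as.character(canonical), as.character(synonym)),
         stats::setNames(unique(as.character(canonical)),
                         unique(as.character(canonical))))
  m <- m[!duplicated(names(m))]
  class(m) <- "alias_map"
  m
}

#' Read a miRBase-style alias dictionary
#'
#' Expects the miRBase `aliases.txt` dialect: one record per line, a
#' canonical accession or name, a TAB, then a semicolon-terminated list of
#' synonyms.
#'
#' @param path Path to the aliases file (optionally gzipped).
#' @return An [alias_map()].
#' @export
read_mirna_aliases <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  canon <- vapply(parts, `[`, "", 1L)
  syn_field <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else "", "")
  syn_lists <- strsplit(sub(";$", "", syn_field), ";", fixed = TRUE)
  n_syn <- lengths(syn_lists)
  alias_map(canonical = rep(canon, n_syn), synonym = unlist(syn_lists))
}

#' Read a two-column source-id to gene-id map
#'
#' @param path TSV with two columns: source id (e.g. transcript), gene id.
#' @param header Whether the file has a header row.
#' @return An [alias_map()] from source id to gene id.
#' @export
read_gene_map <- function(path, header = TRUE) {
  t <- utils::read.delim(path, header = header, colClasses = "character")
  if (ncol(t) < 2L) stop("gene map must have two columns: ", path)
  alias_map(canonical = t[[2L]], synonym = t[[1L]])
}

# Apply an alias map to an id vector; ids absent from the map pass through.
# Returns the mapped vector with an attribute `n_unmapped`.
apply_alias <- function(ids, map) {
  if (is.null(map) || !length(map)) {
    return(structure(ids, n_unmapped = length(ids)))
  }
  hit <- ids %in% names(map)
  out <- ids
  out[hit] <- unname(map[ids[hit]])
  structure(out, n_unmapped = sum(!hit))
}

#' Write / read the canonical interaction TSV
#'
#' All mirfuse outputs round-trip through one documented five-column TSV:
#' `mirna_id`, `gene_id`, `raw_score`, `norm_score`, `db_name`.
#'
#' @param db A `scored_db`.
#' @param path Output path.
#' @return `path`, invisibly (`write_canonical_tsv`); a `scored_db`
#'   (`read_canonical_tsv`).
#' @export
write_canonical_tsv <- function(db, path) {
  out <- db$interactions[, c("mirna_id", "gene_id", "raw_score", "norm_score")]
  out$db_name <- db$name
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_canonical_tsv
#' @param direction,level Passed to [scored_db()] when reading back.
#' @export
read_canonical_tsv <- function(path, direction = "higher_is_better",
                               level = "gene") {
  t <- utils::read.delim(path, colClasses = c(
    mirna_id = "character", gene_id = "character", raw_score = "numeric",
    norm_score = "numeric", db_name = "character"
  ))
  scored_db(name = t$db_name[1L],
            interactions = t[, c("mirna_id", "gene_id", "raw_score",
                                 "norm_score")],
            direction = direction, level = level)
}
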