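test_that("interaction tables parse, drop malformed rows and deduplicate", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna\tgene\tscore",
               "hsa-miR-1\tTP53\t0.9",
               "hsa-miR-1\tKRAS\t0.4",
               "hsa-miR-2\tTP53\t0.7"), tf)
  db <- read_interaction_table(tf)
  expect_s3_class(db, "scored_db")
  expect_equal(db_size(db), 3L)
  expect_equal(sort(db$interactions$raw_score), c(0.4, 0.7, 0.9))

  # malformed score row is dropped, not fatal
  writeLines(c("mirna\tgene\tscore",
               "hsa-miR-1\tTP53\t0.9",
               "hsa-miR-1\tKRAS\tnot_a_number"), tf)
  expect_message(db2 <- read_interaction_table(tf), "dropped 1")
  expect_equal(db_size(db2), 1L)

  # duplicated pair keeps the most confident score
  writeLines(c("mirna\tgene\tscore",
               "hsa-miR-1\tTP53\t0.2",
               "hsa-miR-1\tTP53\t0.8"), tf)
  db3 <- suppressMessages(read_interaction_table(tf))
  expect_equal(db_size(db3), 1L)
  expect_equal(db3$interactions$raw_score, 0.8)
  # for energy-like scores the lower one is the most confident
  db4 <- suppressMessages(
    read_interaction_table(tf, direction = "lower_is_better"))
  expect_equal(db4$interactions$raw_score, 0.2)

  # missing column and empty table are explicit errors
  writeLines(c("mirna\tgene", "a\tb"), tf)
  expect_error(read_interaction_table(tf), "score")
  writeLines("mirna\tgene\tscore", tf)
  expect_error(read_interaction_table(tf), "empty")
})

test_that("harmonization maps ids, collapses transcripts and is idempotent", {
  mirna_map <- alias_map(canonical = "hsa-miR-21-5p", synonym = "hsa-miR-21")
  gene_map <- alias_map(canonical = c("GENE1", "GENE1"),
                        synonym = c("ENST001", "ENST002"))
  db <- make_db("t", rep("hsa-miR-21", 2), c("ENST001", "ENST002"),
                c(0.3, 0.9), level = "transcript")
  h <- suppressMessages(harmonize(db, mirna_map, gene_map))
  expect_equal(h$level, "gene")
  expect_equal(db_size(h), 1L)
  expect_equal(h$interactions$mirna_id, "hsa-miR-21-5p")
  expect_equal(h$interactions$gene_id, "GENE1")
  # two transcripts of one gene: the higher-confidence score wins
  expect_equal(h$interactions$raw_score, 0.9)
  # idempotent: canonical ids map to themselves
  h2 <- harmonize(h, mirna_map, gene_map)
  expect_identical(h$interactions, h2$interactions)
  # empty maps are the identity
  db_gene <- make_db("g", "m1", "G1", 0.5)
  expect_identical(harmonize(db_gene)$interactions, db_gene$interactions)
  # unknown ids pass through and are counted
  expect_message(harmonize(make_db("u", "miR-x", "Gx", 1), mirna_map,
                           gene_map),
                 "not in the alias dictionary")
})

test_that("miRBase-style alias files and two-column gene maps are read", {
  af <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("MIMAT0000076\thsa-miR-21;hsa-miR-21-5p;",
               "MIMAT0004494\thsa-miR-21*;hsa-miR-21-3p;"), af)
  m <- read_mirna_aliases(af)
  expect_equal(unname(m["hsa-miR-21"]), "MIMAT0000076")
  expect_equal(unname(m["hsa-miR-21-3p"]), "MIMAT0004494")
  # canonical ids map to themselves
  expect_equal(unname(m["MIMAT0000076"]), "MIMAT0000076")

  gf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript\tgene", "ENST1\tG1", "ENST2\tG1"), gf)
  g <- read_gene_map(gf)
  expect_equal(unname(g[c("ENST1", "ENST2")]), c("G1", "G1"))
})

test_that("min-max normalization maps the best score to 1 in either direction", {
  db <- make_db("hi", paste0("m", 1:3), paste0("g", 1:3), c(2, 4, 6))
  expect_equal(normalize_minmax(db)$interactions$norm_score, c(0, 0.5, 1))
  # free energies: lower is better
  en <- make_db("en", paste0("m", 1:3), paste0("g", 1:3), c(-20, -10, 0),
                direction = "lower_is_better")
  expect_equal(normalize_minmax(en)$interactions$norm_score, c(1, 0.5, 0))
  # already [0, 1]: unchanged
  id <- make_db("id", paste0("m", 1:3), paste0("g", 1:3), c(0, 0.25, 1))
  expect_equal(normalize_minmax(id)$interactions$norm_score, c(0, 0.25, 1))
  # degenerate: constant scores -> all 1, with a warning
  cst <- make_db("c", paste0("m", 1:3), paste0("g", 1:3), rep(5, 3))
  expect_warning(ncst <- normalize_minmax(cst), "single distinct score")
  expect_equal(ncst$interactions$norm_score, rep(1, 3))
})

test_that("min-max normalization is idempotent", {
  set.seed(11)
  db <- make_db("x", paste0("m", 1:50), paste0("g", 1:50), rnorm(50))
  once <- normalize_minmax(db)
  once$interactions$raw_score <- once$interactions$norm_score
  twice <- normalize_minmax(once)
  expect_equal(twice$interactions$norm_score, once$interactions$norm_score)
})

test_that("rank/CDF normalization yields the distribution-free grid", {
  db <- make_db("r", paste0("m", 1:4), paste0("g", 1:4),
                c(10, 3, 7, 100))
  n <- normalize_rank_cdf(db)
  expect_equal(sort(n$interactions$norm_score), c(0.25, 0.5, 0.75, 1))
  # best raw score gets exactly 1
  expect_equal(n$interactions$norm_score[which.max(db$interactions$raw_score)], 1)
  # all tied -> all equal (sharing the maximum rank of the group)
  tied <- make_db("t", paste0("m", 1:3), paste0("g", 1:3), rep(2, 3))
  expect_equal(normalize_rank_cdf(tied)$interactions$norm_score, rep(1, 3))
  # single interaction -> 1
  one <- make_db("o", "m", "g", 0.123)
  expect_equal(normalize_rank_cdf(one)$interactions$norm_score, 1)
  # lower_is_better reverses confidence order
  lo <- make_db("lo", paste0("m", 1:4), paste0("g", 1:4), c(10, 3, 7, 100),
                direction = "lower_is_better")
  nlo <- normalize_rank_cdf(lo)
  expect_equal(nlo$interactions$norm_score[which.min(lo$interactions$raw_score)], 1)
})

test_that("rank/CDF grid depends only on n and the tie pattern", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    raw <- sample(seq(-5, 5, by = 0.5), n, replace = TRUE)
    db <- make_db("p", paste0("m", 1:n), paste0("g", 1:n), raw)
    got <- normalize_rank_cdf(db)$interactions$norm_score
    expect_true(all(got > 0 & got <= 1))
    # monotone transform invariance: exp() preserves order and ties
    db2 <- make_db("p2", paste0("m", 1:n), paste0("g", 1:n), exp(raw))
    expect_equal(normalize_rank_cdf(db2)$interactions$norm_score, got)
    # sorted values form rank_max/n for the observed tie pattern
    expect_equal(sort(unique(got)),
                 sort(unique(rank(raw, ties.method = "max") / n)))
  }
})

test_that("the universe is the union of predicted pairs only", {
  a <- make_db("a", c("m1", "m1", "m2"), c("g1", "g2", "g1"), c(1, 2, 3))
  b <- make_db("b", c("m1", "m2", "m9"), c("g2", "g1", "g9"), c(1, 2, 3))
  gold <- make_gold(c("m1\tg2", "mX\tgX"))
  u <- build_universe(list(a, b), gold)
  expect_equal(length(u$keys), 4L)  # 2 overlapping of 3 + 3
  expect_equal(u$validated_count, 1L)
  # gold pair never predicted stays outside the universe
  expect_false("mX\tgX" %in% u$keys)
  expect_equal(u$n_gold_outside, 1L)
  # order-invariance over the database list
  u2 <- build_universe(list(b, a), gold)
  expect_identical(u$keys, u2$keys)
  # single database: universe equals its pair set
  u3 <- build_universe(list(a), gold)
  expect_setequal(u3$keys, keys_of(a))
  expect_error(build_universe(list(), gold), "at least one")
})

test_that("canonical TSV round-trips a database", {
  db <- normalize_minmax(make_db("rt", paste0("m", 1:5), paste0("g", 1:5),
                                 c(0.1, 5, 2, 3.7, 4)))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_canonical_tsv(db, tf)
  back <- read_canonical_tsv(tf)
  expect_equal(back$name, "rt")
  expect_equal(back$interactions$norm_score, db$interactions$norm_score)
  expect_equal(back$interactions$raw_score, db$interactions$raw_score)
})
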