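test_that("equal-count bins preserve the exact validated-count identity", {
  # 10 interactions, 2 bins, 4 of the top 5 validated
  db <- make_db("b", paste0("m", 1:10), paste0("g", 1:10), 10:1,
                norm = seq(1, 0.1, by = -0.1))
  gold <- make_gold(paste0("m", c(1, 2, 3, 4, 7), "\tg", c(1, 2, 3, 4, 7)))
  bins <- bin_validation_fraction(db, gold, n_bins = 2)
  expect_equal(nrow(bins), 2L)
  expect_equal(bins$count, c(5L, 5L))
  # bins are reported in increasing score order: top bin is the second row
  expect_equal(bins$fraction[2], 4 / 5)
  expect_equal(bins$fraction[1], 1 / 5)
  # integer identity before any smoothing
  expect_identical(sum(bins$count * bins$fraction), 5)

  none <- bin_validation_fraction(db, make_gold("x\tx"), 5)
  expect_true(all(none$fraction == 0))
  all_v <- bin_validation_fraction(db, make_gold(keys_of(db)), 5)
  expect_true(all(all_v$fraction == 1))
  expect_error(bin_validation_fraction(db, gold, 11), "exceeds")
  expect_error(bin_validation_fraction(db, gold, 1), "at least 2")
})

test_that("calibration splines reproduce collinear and constant bins", {
  mk_bins <- function(mid, frac) {
    data.frame(midpoint = mid, lower = mid, upper = mid,
               count = rep(10L, length(mid)),
               validated = as.integer(10 * frac), fraction = frac)
  }
  # collinear points: the smoothing spline has zero penalty and zero
  # residual on the interpolating line, so it reproduces it at the knots
  mid <- seq(0.05, 0.95, length.out = 10)
  lin <- fit_calibration(mk_bins(mid, 0.1 + 0.8 * mid))
  expect_equal(predict_calibration(lin, mid), 0.1 + 0.8 * mid,
               tolerance = 1e-6)
  # constant fractions
  cst <- fit_calibration(mk_bins(mid, rep(0.3, 10)))
  expect_equal(predict_calibration(cst, c(0.1, 0.5, 0.9)), rep(0.3, 3),
               tolerance = 1e-6)
  # evaluation beyond the fitted range clamps, stays in [0, 1]
  expect_equal(predict_calibration(lin, -5), predict_calibration(lin, mid[1]))
  expect_true(all(predict_calibration(lin, seq(-1, 2, 0.1)) >= 0 &
                    predict_calibration(lin, seq(-1, 2, 0.1)) <= 1))
  # degenerate identical midpoints fall back to a constant fit
  expect_message(
    deg <- fit_calibration(mk_bins(rep(0.5, 3), c(0.2, 0.4, 0.6))),
    "degenerate")
  expect_equal(predict_calibration(deg, c(0, 1)), rep(0.4, 2))
})

test_that("feature matrix has mains plus pairwise cross-terms, order-invariant", {
  mkdb <- function(nm, sc) make_db(nm, "m1", "g1", sc, norm = sc)
  dbs <- list(mkdb("B", 0.5), mkdb("A", 0.2), mkdb("C", 0.8))
  X <- probability_features("m1\tg1", dbs, features = "score")
  expect_equal(colnames(X), c("A", "B", "C", "A:B", "A:C", "B:C"))
  expect_equal(unname(X[1, ]), c(0.2, 0.5, 0.8, 0.1, 0.16, 0.4))
  # database input order does not matter
  X2 <- probability_features("m1\tg1", rev(dbs), features = "score")
  expect_identical(X, X2)
  # absent pair gets the fill; its cross-terms vanish with fill = 0
  dbs2 <- list(mkdb("A", 0.4), make_db("B", "m9", "g9", 1, norm = 1))
  X3 <- probability_features("m1\tg1", dbs2, features = "score")
  expect_equal(unname(X3[1, ]), c(0.4, 0, 0))
})

test_that("LRS predictions reproduce the fitted linear form row by row", {
  set.seed(9)
  ens <- generate_ensemble(informative_spec(7, n_true = 500, db_true = 300,
                                            db_false = 700))
  dbs <- normalize_all(ens$dbs)
  u <- build_universe(dbs, ens$gold)
  cfg <- lrs_config(n_bins = 20)
  model <- fit_lrs(dbs, ens$gold, u, cfg)
  cs <- lrs_combine(dbs, ens$gold, u, model = model)
  expect_true(all(cs$scores > 0 & cs$scores < 1))
  # independent re-evaluation: matrix multiply + inverse logit
  X <- probability_features(u$keys, dbs, model$curves)
  eta <- model$intercept +
    drop(X[, names(model$coefficients)] %*% model$coefficients)
  expect_equal(cs$scores, 1 / (1 + exp(-eta)), tolerance = 1e-12)
  # all-zero features collapse to the intercept
  expect_equal(unname(predict(model,
                              "absent\tpair",
                              dbs)),
               1 / (1 + exp(-model$intercept)), tolerance = 1e-12)
})

test_that("unpenalized LRS satisfies the logistic score equation", {
  set.seed(10)
  ens <- generate_ensemble(informative_spec(8, n_true = 500, db_true = 300,
                                            db_false = 700))
  dbs <- normalize_all(ens$dbs)
  u <- build_universe(dbs, ens$gold)
  cs <- lrs_combine(dbs, ens$gold, u, config = lrs_config(n_bins = 20))
  expect_equal(mean(cs$scores), u$validated_count / length(u$keys),
               tolerance = 1e-6)
})

test_that("LRS ranks at least as well as every individual database", {
  set.seed(12)
  aucs <- replicate(3, {
    s <- sample.int(1e6, 1)
    ens <- generate_ensemble(informative_spec(s, n_true = 800,
                                              db_true = 500,
                                              db_false = 1000))
    dbs <- normalize_all(ens$dbs)
    u <- build_universe(dbs, ens$gold)
    cs <- lrs_combine(dbs, ens$gold, u, config = lrs_config(n_bins = 30))
    lrs_auc <- roc_curve(cs, ens$gold, u,
                         include_unpredicted_gold = FALSE)$auc
    best_db <- max(vapply(dbs, own_pairs_auc, 0, gold = ens$gold))
    lrs_auc - best_db
  })
  expect_true(all(aucs >= -0.01))
})

test_that("cross-validation guards against degenerate folds", {
  db <- normalize_minmax(make_db("s", paste0("m", 1:12), paste0("g", 1:12),
                                 1:12))
  gold <- make_gold(paste0("m", 1:3, "\tg", 1:3))
  u <- build_universe(list(db), gold)
  expect_error(cross_validated_auc(list(db), gold, u, folds = 1), "at least 2")
  expect_error(cross_validated_auc(list(db), gold, u, folds = 10,
                                   config = lrs_config(n_bins = 3)),
               "fewer folds")
})

test_that("LRS models serialize to text and round-trip exactly", {
  set.seed(21)
  n <- 400
  x <- runif(n)
  lab <- runif(n) < 1 / (1 + exp(-(-1 + 2 * x)))
  keys <- paste0("m", 1:n, "\tg", 1:n)
  db <- make_db("solo", paste0("m", 1:n), paste0("g", 1:n), x, norm = x)
  gold <- make_gold(keys[lab])
  u <- build_universe(list(db), gold)
  m <- fit_lrs(list(db), gold, u, lrs_config(features = "score"))
  tf <- withr::local_tempfile(fileext = ".txt")
  write_lrs_model(m, tf)
  back <- read_lrs_model(tf)
  expect_identical(back$intercept, m$intercept)
  expect_identical(back$coefficients, m$coefficients)
  expect_identical(back$feature_spec$columns, m$feature_spec$columns)
  # restored score-feature model predicts identically
  expect_equal(predict(back, u$keys, list(db)),
               predict(m, u$keys, list(db)), tolerance = 1e-15)
})
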