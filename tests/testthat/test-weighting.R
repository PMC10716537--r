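test_that("equal-frequency discretization: splits, ties, degenerate input", {
  b <- discretize_equal_frequency(c(1, 2, 3, 4), B = 2)
  expect_equal(as.integer(b), c(1L, 1L, 2L, 2L))

  expect_warning(one <- discretize_equal_frequency(rep(3, 5), B = 4),
                 "constant")
  expect_equal(nlevels(one), 1)

  merged <- discretize_equal_frequency(c(1, 1, 1, 1, 9, 9), B = 3)
  expect_equal(nlevels(droplevels(merged)), 2)
  expect_equal(as.integer(factor(as.integer(merged))), c(1, 1, 1, 1, 2, 2))

  expect_error(discretize_equal_frequency(1:4, B = 1), "B must be")
})

test_that("entropy-family weighters reproduce hand-computed values", {
  f <- factor(c("a", "a", "a", "b"))
  y <- factor(c("+", "+", "-", "-"))
  h <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  ig <- 1 - 3 / 4 * h(2 / 3)
  expect_equal(weight_info_gain(f, y), ig, tolerance = 1e-12)
  expect_equal(ig, 0.3112781, tolerance = 1e-6)
  expect_equal(weight_gain_ratio(f, y), ig / h(1 / 4), tolerance = 1e-12)
  expect_equal(weight_symmetric_uncertainty(f, y), 2 * ig / (h(1 / 4) + 1),
               tolerance = 1e-12)
  expect_equal(weight_gini(f, y), 0.5 - 3 / 4 * (4 / 9), tolerance = 1e-12)

  # perfect predictor and constant feature
  yp <- factor(c("+", "+", "-", "-"))
  fp <- factor(c("u", "u", "v", "v"))
  expect_equal(weight_info_gain(fp, yp), 1)
  expect_equal(weight_gain_ratio(fp, yp), 1)
  expect_equal(weight_symmetric_uncertainty(fp, yp), 1)
  fc <- factor(rep("u", 4))
  expect_equal(weight_info_gain(fc, yp), 0)
  expect_equal(weight_gain_ratio(fc, yp), 0)
  expect_equal(weight_gini(fc, yp), 0)
})

test_that("chi-squared weighter matches the 2x2 closed form", {
  f <- factor(rep(c("a", "b"), each = 5))
  y10 <- factor(rep(c("+", "-"), each = 5))        # table [[5,0],[0,5]]
  expect_equal(weight_chi_squared(f, y10), 10)
  y41 <- factor(c("+", "+", "+", "+", "-", "+", "-", "-", "-", "-"))
  expect_equal(weight_chi_squared(f, y41), 3.6)    # table [[4,1],[1,4]]
  # identical class proportions per bin -> independence -> 0
  yind <- factor(rep(c("+", "+", "-", "-"), 2))
  find <- factor(rep(c("a", "b"), each = 4))
  expect_equal(weight_chi_squared(find, yind), 0)
})

test_that("rule weighter equals exhaustive best-split search", {
  expect_equal(weight_rule(c(1, 2, 3, 4), factor(c("+", "+", "-", "+"))),
               0.75)
  expect_equal(weight_rule(factor(c("u", "u", "v", "v")),
                           factor(c("+", "+", "-", "-"))), 1.0)
  expect_equal(weight_rule(rep(2, 4), factor(c("+", "+", "-", "-"))), 0.5)

  set.seed(11)
  for (rep in 1:30) {
    tab <- random_small_table()
    expect_equal(weight_rule(tab$f, tab$y), oracle_rule(tab$f, tab$y),
                 info = paste("rule mismatch rep", rep))
  }
})

test_that("each table weighter agrees with brute-force enumeration on small tables", {
  set.seed(23)
  for (rep in 1:60) {
    tab <- random_small_table(n = sample(4:8, 1), bins = sample(2:3, 1))
    fb <- crsig:::as_bins(tab$f, tab$bins)
    expect_equal(weight_info_gain(tab$f, tab$y, tab$bins),
                 oracle_info_gain(fb, tab$y), tolerance = 1e-10)
    expect_equal(weight_gain_ratio(tab$f, tab$y, tab$bins),
                 oracle_gain_ratio(fb, tab$y), tolerance = 1e-10)
    expect_equal(weight_symmetric_uncertainty(tab$f, tab$y, tab$bins),
                 oracle_symmetric_uncertainty(fb, tab$y), tolerance = 1e-10)
    expect_equal(weight_chi_squared(tab$f, tab$y, tab$bins),
                 oracle_chi_squared(fb, tab$y), tolerance = 1e-10)
    expect_equal(weight_gini(tab$f, tab$y, tab$bins),
                 oracle_gini_index(fb, tab$y), tolerance = 1e-10)
  }
})

test_that("Relief: closed-form cases and brute-force oracle agreement", {
  ft <- feature_table_from(cbind(sep = c(0, 0, 1, 1),
                                 const = c(2, 2, 2, 2)),
                           label = c("control", "control", "CR", "CR"))
  w <- weight_relief(ft, k = 1)
  expect_equal(unname(w["sep"]), 1)
  expect_equal(unname(w["const"]), 0)
  expect_true(all(w >= -1 & w <= 1))

  expect_error(
    weight_relief(feature_table_from(cbind(x = 1:3),
                                     label = c("control", "CR", "CR")),
                  k = 1),
    ">=2 per class")

  set.seed(31)
  for (rep in 1:15) {
    n <- 6
    x <- cbind(a = runif(n), b = runif(n), c = round(runif(n), 1))
    lab <- c("control", "control", "control", "CR", "CR", "CR")
    tis <- sample(c("t1", "t2"), n, replace = TRUE)
    ft <- feature_table_from(x, lab, tissue = tis)
    k <- sample(1:2, 1)
    got <- weight_relief(ft, k = k)
    want <- oracle_relief(as.data.frame(ft), lab, k)
    expect_equal(got, want[names(got)], tolerance = 1e-12,
                 info = paste("relief rep", rep))
  }
})

test_that("Relief is invariant to affine rescaling of a numeric feature", {
  set.seed(41)
  n <- 10
  x <- cbind(f1 = rnorm(n), f2 = runif(n))
  lab <- rep(c("control", "CR"), each = 5)
  ft1 <- feature_table_from(x, lab)
  x2 <- x; x2[, "f1"] <- 100 + 7 * x2[, "f1"]
  ft2 <- feature_table_from(x2, lab)
  expect_equal(weight_relief(ft1, k = 3), weight_relief(ft2, k = 3),
               tolerance = 1e-12)
})

test_that("min-max normalization: affine map, degenerate warning", {
  expect_equal(unname(normalize_weights(c(a = 2, b = 4, c = 6))),
               c(0, 0.5, 1))
  expect_equal(unname(normalize_weights(c(a = -0.2, b = 0.1, c = 0.4))),
               c(0, 0.5, 1))
  expect_warning(z <- normalize_weights(c(a = 3.3, b = 3.3)), "all raw")
  expect_equal(unname(z), c(0, 0))
})

test_that("weigh_features: normalized range, irrelevant-feature stability", {
  set.seed(51)
  gen <- simulate_counts(sim_config(seed = 51, n_genes = 40, n_spike = 4,
                                    tissues = c("hyp", "amy"),
                                    n_per_group = 4))
  ft <- build_feature_table(gen$counts, gen$samples)
  w <- weigh_features(ft, bins = 4, relief_k = 3)
  expect_setequal(colnames(w), crsig:::WEIGHTING_ALGORITHMS)
  expect_true(all(w >= 0 & w <= 1))
  expect_equal(nrow(w), 41)  # 40 genes + tissue

  # adding a permuted (irrelevant) copy never changes other features' raw
  # table-based weights
  raw1 <- attr(w, "raw")
  ft2 <- ft
  ft2$permuted <- sample(ft[[1]])
  ft2 <- ft2[, c(setdiff(names(ft2), "tissue"), "tissue")]
  attr(ft2, "label") <- feature_label(ft)
  class(ft2) <- class(ft)
  w2 <- weigh_features(ft2, bins = 4, relief_k = 3)
  raw2 <- attr(w2, "raw")
  shared <- rownames(raw1)
  tab_algos <- c("info_gain", "gain_ratio", "chi_squared", "gini",
                 "uncertainty", "rule")
  expect_equal(raw2[shared, tab_algos], raw1[shared, tab_algos],
               tolerance = 1e-12)
})
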