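com11 <- mock11_community()
exp11 <- expected_proportions(com11)

test_that("euclidean distance basics and the published-summary value", {
  expect_equal(euclidean_distance(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(euclidean_distance(c(1, 0), c(0, 1)), sqrt(2))
  expect_error(euclidean_distance(c(1, 0), c(1, 0, 0)), "length")
  p <- setNames(c(0.5, 0.5), c("a", "b"))
  q <- setNames(c(0.5, 0.5), c("b", "a"))
  expect_error(euclidean_distance(p, q), "taxa")

  # distances of the packaged per-method mean proportions to expectation,
  # frozen from direct evaluation of the formula on the published values
  obs <- mock11_observed()
  d <- vapply(sort(unique(obs$method)), function(m) {
    sub <- obs[obs$method == m, ]
    v <- sub$mean_pct[match(com11$name, sub$taxon)] / 100
    euclidean_distance(v, unname(exp11))
  }, numeric(1))
  expect_equal(unname(d), c(0.1992, 0.1657, 0.4258, 0.2192, 0.4224, 0.3128),
               tolerance = 1e-3)
})

test_that("representation scores: zeros at expectation, bias increases them", {
  exact <- round(exp11 * 52000)
  tab <- make_counts(list(exact, exact))
  expect_equal(unname(representation_scores(tab, exp11)), c(0, 0))

  # single-replicate reduction
  tab1 <- count_table(matrix(exact + c(50, rep(0, 10)),
                             dimnames = list(names(exact), NULL)))
  expect_equal(unname(representation_scores(tab1, exp11)),
               euclidean_distance(observed_proportions(tab1)[, 1], exp11))

  # a method with lysis bias scores worse than an unbiased one at the
  # same theta and depth (paired simulation, majority vote)
  eff_bias <- rep(1, 11); eff_bias[5] <- 0.2; eff_bias[7] <- 3
  wins <- vapply(1:50, function(s) {
    cfg <- simulation_config(com11,
                             list(fair = 1, biased = eff_bias),
                             theta = 100, depth = 2000, seed = s)
    fair <- simulate_counts(cfg, "fair")
    biased <- simulate_counts(cfg, "biased")
    mean(representation_scores(biased, exp11)) >
      mean(representation_scores(fair, exp11))
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("reproducibility scores behave at fixed points and outliers", {
  col <- c(10, 30, 60)
  tab <- make_counts(list(col, col, col))
  expect_equal(unname(reproducibility_scores(tab)), c(0, 0, 0))
  expect_error(reproducibility_scores(count_table(matrix(col))),
               "at least two")

  # two equal-depth replicates are equidistant from the pooled baseline
  tab2 <- make_counts(list(c(10, 90), c(30, 70)))
  d <- reproducibility_scores(tab2)
  expect_equal(d[[1]], d[[2]])

  # a constructed outlier has the largest deviation
  tab3 <- make_counts(list(col, col, col, c(60, 30, 10)))
  d3 <- reproducibility_scores(tab3)
  expect_equal(unname(which.max(d3)), 4L)
})

test_that("exact Wilcoxon p matches the enumeration oracle (exhaustive n <= 6)", {
  # the textbook separated case first: p = 2/20
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)

  set.seed(15)
  for (nx in 2:6) {
    for (ny in 2:6) {
      x <- sample(seq_len(100), nx)
      y <- sample(setdiff(seq_len(100), x), ny)
      got <- wilcoxon_rank_sum(x, y, mode = "exact")
      expect_identical(got$mode_used, "exact")
      expect_equal(got$p_value, wilcoxon_enum_oracle(x, y),
                   tolerance = 1e-12,
                   info = sprintf("nx=%d ny=%d", nx, ny))
    }
  }
})

test_that("Wilcoxon falls back to the corrected normal approximation", {
  x <- c(1, 2, 2, 3)  # tie forces the fallback
  y <- c(4, 5, 6, 7)
  got <- wilcoxon_rank_sum(x, y, mode = "exact")
  expect_identical(got$mode_used, "normal")
  # identical samples in normal mode: no evidence of a shift
  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3), mode = "normal")
  expect_gt(same$p_value, 0.9)
})

test_that("Fligner-Killeen calibration, power and degenerate input", {
  set.seed(31)
  rej <- vapply(1:500, function(i) {
    g1 <- rnorm(10); g2 <- rnorm(10)
    fligner_killeen(list(g1, g2))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)

  # 10x spread ratio at n = 20 is detected
  set.seed(32)
  g_wide <- rnorm(20, sd = 10); g_narrow <- rnorm(20, sd = 1)
  expect_lt(fligner_killeen(list(g_wide, g_narrow))$p_value, 0.05)

  # all observations at their group medians: statistic 0, p 1
  res <- fligner_killeen(list(c(5, 5, 5), c(2, 2, 2)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("Spearman correlation: monotone cases, ties, constants", {
  expect_equal(spearman_correlation(1:5, c(2, 4, 9, 16, 100))$rho, 1)
  expect_equal(spearman_correlation(1:5, 5:1)$rho, -1)
  # tie case against the definition oracle (Pearson on average ranks)
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8)
  oracle <- stats::cor(rank(x), rank(y))
  expect_equal(spearman_correlation(x, y)$rho, oracle, tolerance = 1e-12)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
})

test_that("Bonferroni adjustment scales and caps", {
  expect_equal(bonferroni_adjust(c(0.01, 0.20), m = 2), c(0.02, 0.40))
  expect_equal(bonferroni_adjust(0.9, m = 15), 1)
  expect_equal(choose(6, 2), 15)  # the all-pairs family for six methods
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("compare_methods runs the full pipeline and detects strong bias", {
  eff_bias <- rep(1, 11); eff_bias[7] <- 6; eff_bias[1] <- 0.1
  cfg <- simulation_config(com11, list(fair = 1, biased = eff_bias),
                           theta = 500, depth = 2000, seed = 99)
  tables <- list(fair = simulate_counts(cfg, "fair"),
                 biased = simulate_counts(cfg, "biased"))
  rep <- compare_methods(tables, exp11)
  expect_s3_class(rep, "evaluation_report")
  row <- rep$representation_tests
  expect_equal(nrow(row), 1)
  expect_lt(row$adjusted_p, 0.05)
  expect_gt(mean(rep$representation$biased), mean(rep$representation$fair))
  # block comparisons exist because simulate_counts fills metadata
  expect_false(is.null(rep$block_tests$fair$experimenter))

  # identical tables: nothing is significant
  same <- compare_methods(list(a = tables$fair, b = tables$fair), exp11)
  expect_gte(min(same$representation_tests$adjusted_p), 0.99)

  # invariant to input order up to relabeling
  rep_rev <- compare_methods(rev(tables), exp11)
  expect_equal(rep_rev$representation, rep$representation)
  expect_equal(rep_rev$representation_tests, rep$representation_tests)
})

test_that("evaluation reports round-trip through JSON and export distances", {
  cfg <- simulation_config(com11, list(m1 = 1, m2 = 1), theta = 80,
                           depth = 500, seed = 7)
  tables <- list(m1 = simulate_counts(cfg, "m1"),
                 m2 = simulate_counts(cfg, "m2"))
  rep <- compare_methods(tables, exp11)
  path <- withr::local_tempfile(fileext = ".json")
  write_evaluation_report(rep, path)
  back <- read_evaluation_report(path)
  expect_equal(back$methods, rep$methods)
  expect_equal(back$representation$m1, rep$representation$m1)
  expect_equal(back$representation_tests$adjusted_p,
               rep$representation_tests$adjusted_p)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_distance_tsv(rep, tsv)
  long <- read.delim(tsv)
  expect_equal(nrow(long), 2 * 2 * 8)  # metrics x methods x replicates
})

test_that("yield-distance correlation wiring matches replicates to yields", {
  cfg <- simulation_config(com11, list(m1 = 1, m2 = 1), theta = 80,
                           depth = 500, seed = 13)
  tables <- list(m1 = simulate_counts(cfg, "m1"),
                 m2 = simulate_counts(cfg, "m2"))
  set.seed(5)
  yields <- yield_table(data.frame(
    method = rep(c("m1", "m2"), each = 8),
    sample = "mock",
    replicate = rep(1:8, 2),
    concentration = rlnorm(16)))
  rep <- compare_methods(tables, exp11, yields = yields)
  expect_named(rep$correlation, c("within", "across"))
  expect_true(is.finite(rep$correlation$across$rho))
  expect_equal(rep$correlation$within$m1$n, 8)
  # mismatched replicate counts are refused
  bad <- yields[-1, ]
  expect_error(compare_methods(tables, exp11, yields = yield_table(bad)),
               "records for method")
})

test_that("pooled-baseline distance never exceeds the worst replicate distance", {
  # convexity check: the grand-proportion vector is a convex combination
  # of replicate proportion vectors
  for (s in 1:20) {
    set.seed(600 + s)
    tab <- count_table(mockbench:::rdm_counts(rep(1000, 5), exp11, 30))
    d_grand <- euclidean_distance(grand_proportions(tab), exp11)
    expect_lte(d_grand, max(representation_scores(tab, exp11)) + 1e-12)
  }
})
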