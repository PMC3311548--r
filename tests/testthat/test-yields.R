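# Helper: balanced synthetic yield table on the log scale.
sim_yield_table <- function(methods = 4, samples = 3, reps = 2,
                            method_effect = 0, block_sd = 0.3,
                            resid_sd = 0.4, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(method = paste0("m", seq_len(methods)),
                      sample = paste0("s", seq_len(samples)),
                      experimenter = c("expA", "expB"),
                      rep = seq_len(reps), stringsAsFactors = FALSE)
  block <- setNames(rnorm(2, 0, block_sd), c("expA", "expB"))
  meff <- setNames(seq_len(methods) * method_effect, paste0("m", seq_len(methods)))
  grid$concentration <- exp(meff[grid$method] + block[grid$experimenter] +
                              rnorm(nrow(grid), 0, resid_sd))
  grid$replicate <- paste(grid$experimenter, grid$rep, sep = "_")
  grid$day <- NA_character_
  yield_table(grid[, c("method", "sample", "replicate", "experimenter",
                       "day", "concentration")])
}

test_that("log transform is natural log, guarded, and applied once", {
  yt <- yield_table(data.frame(method = "m", sample = "s", replicate = 1:3,
                               concentration = c(1, exp(1), 10)))
  lt <- log_transform_yields(yt)
  expect_equal(lt$concentration, c(0, 1, log(10)))
  expect_equal(exp(lt$concentration), yt$concentration, tolerance = 1e-12)
  expect_error(log_transform_yields(lt), "already")
  yt0 <- yield_table(data.frame(method = "m", sample = "s", replicate = 1:2,
                                concentration = c(0, 1)))
  expect_error(log_transform_yields(yt0), "record\\(s\\) 1")
})

test_that("split-plot ANOVA degrees of freedom follow the closed forms", {
  # 6 methods x 12 samples x 2 blocks x 4 reps
  yt <- sim_yield_table(methods = 6, samples = 12, reps = 4, seed = 3)
  an <- splitplot_anova(yt)
  get <- function(src, col) an[an$source == src, col]
  expect_equal(get("method", "df"), 5)
  expect_equal(get("block:method", "df"), 5)
  expect_equal(get("sample", "df"), 11)
  expect_equal(get("method:sample", "df"), 55)
  expect_equal(sum(an$df), nrow(as.data.frame(yt)) - 1)
  # method F is tested against the whole-plot error stratum
  expect_equal(get("method", "error_stratum"), "block:method")
})

test_that("ANOVA sums of squares are non-negative and decompose the total", {
  for (s in 1:10) {
    yt <- sim_yield_table(methods = 3, samples = 4, reps = 2,
                          method_effect = 0.3, seed = 100 + s)
    an <- splitplot_anova(yt)
    expect_true(all(an$sum_sq >= -1e-10))
    y <- log(as.data.frame(yt)$concentration)
    expect_equal(sum(an$sum_sq), sum((y - mean(y))^2), tolerance = 1e-8)
  }
})

test_that("split-plot ANOVA rejects unbalanced designs", {
  yt <- sim_yield_table(methods = 3, samples = 2, reps = 2, seed = 5)
  expect_error(splitplot_anova(yt[-1, ]), "unbalanced")
})

test_that("split-plot ANOVA detects a strong method effect", {
  # 2x spread on the log scale; p < 0.01 in nearly all runs
  hits <- vapply(1:40, function(s) {
    yt <- sim_yield_table(methods = 4, samples = 4, reps = 2,
                          method_effect = log(2), seed = 2000 + s)
    an <- splitplot_anova(yt)
    an[an$source == "method", "p"] < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Tukey HSD per sample: t-test identity at k = 2 and cluster recovery", {
  # q(alpha, 2, df) = sqrt(2) * t(alpha/2, df), so the k = 2 Tukey
  # decision must agree with the two-sample t test
  set.seed(41)
  yt <- sim_yield_table(methods = 2, samples = 1, reps = 6,
                        method_effect = 0.8, block_sd = 0, seed = 41)
  hsd <- tukey_hsd_per_sample(yt, "s1", alpha = 0.05)
  df <- as.data.frame(yt)
  tt <- t.test(log(concentration) ~ method, data = df, var.equal = TRUE)
  # ptukey and pt agree through the q = sqrt(2) t identity, up to the
  # numerical accuracy of ptukey itself
  expect_equal(hsd$p_values["m1", "m2"], tt$p.value, tolerance = 1e-6)
  expect_equal(hsd$significant["m1", "m2"], tt$p.value < 0.05)

  # identical data across methods: never significant
  d <- data.frame(method = rep(c("a", "b"), each = 4), sample = "s",
                  replicate = rep(1:4, 2),
                  concentration = rep(c(1, 1.1, 0.9, 1.05), 2))
  hsd_same <- tukey_hsd_per_sample(yield_table(d), "s")
  expect_false(any(hsd_same$significant))

  # two well-separated clusters of methods
  set.seed(42)
  d2 <- expand.grid(method = paste0("m", 1:6), replicate = 1:4,
                    stringsAsFactors = FALSE)
  d2$sample <- "s"
  base <- ifelse(d2$method %in% c("m1", "m2", "m3"), 5, 0.05)
  d2$concentration <- base * exp(rnorm(nrow(d2), 0, 0.1))
  hsd2 <- tukey_hsd_per_sample(yield_table(d2), "s")
  hi <- c("m1", "m2", "m3"); lo <- c("m4", "m5", "m6")
  expect_true(all(hsd2$significant[hi, lo]))
  expect_false(any(hsd2$significant[hi, hi]))
  expect_false(any(hsd2$significant[lo, lo]))
})

test_that("Tukey significance is monotone in mean separation", {
  set.seed(43)
  noise <- rnorm(8, 0, 0.2)
  prev_sig <- FALSE
  for (gap in c(0.1, 0.5, 1, 2, 4)) {
    d <- data.frame(method = rep(c("a", "b"), each = 4), sample = "s",
                    replicate = rep(1:4, 2),
                    concentration = exp(c(noise[1:4], noise[5:8] + gap)))
    hsd <- tukey_hsd_per_sample(yield_table(d), "s")
    # once significant, larger gaps stay significant
    expect_true(hsd$significant["a", "b"] >= prev_sig)
    prev_sig <- hsd$significant["a", "b"]
  }
})

test_that("compact letter display handles the canonical patterns", {
  lab <- c("w", "x", "y", "z")
  none <- matrix(FALSE, 4, 4, dimnames = list(lab, lab))
  means <- setNames(c(4, 3, 2, 1), lab)
  cld <- compact_letter_display(none, means)
  expect_true(all(cld$letters == "A"))

  all_sig <- !diag(4); dimnames(all_sig) <- list(lab, lab)
  cld2 <- compact_letter_display(all_sig, means)
  expect_equal(unname(cld2$letters[lab]), c("A", "B", "C", "D"))

  # smallest non-transitive chain: 1~2 and 2~3 not significant, 1 vs 3 is
  lab3 <- c("g1", "g2", "g3")
  chain <- matrix(FALSE, 3, 3, dimnames = list(lab3, lab3))
  chain["g1", "g3"] <- chain["g3", "g1"] <- TRUE
  cld3 <- compact_letter_display(chain, setNames(c(3, 2, 1), lab3))
  expect_equal(unname(cld3$letters[lab3]), c("A", "AB", "B"))
  expect_true(letters_consistent(cld3))

  asym <- chain; asym["g1", "g2"] <- TRUE
  expect_error(compact_letter_display(asym, setNames(c(3, 2, 1), lab3)),
               "symmetric")
})

test_that("letter displays satisfy the iff invariant on realizable matrices", {
  # realizable significance structures generated by running Tukey HSD on
  # random clustered data (includes non-transitive borderline patterns)
  for (s in 1:15) {
    set.seed(700 + s)
    k <- sample(3:6, 1)
    centers <- cumsum(runif(k, 0, 1.2))
    d <- expand.grid(method = paste0("m", 1:k), replicate = 1:4,
                     stringsAsFactors = FALSE)
    d$sample <- "s"
    d$concentration <- exp(centers[match(d$method, paste0("m", 1:k))] +
                             rnorm(nrow(d), 0, 0.3))
    hsd <- tukey_hsd_per_sample(yield_table(d), "s")
    cld <- compact_letter_display(hsd$significant, hsd$means)
    expect_true(letters_consistent(cld), info = paste("seed", 700 + s))
  }
})

test_that("yield_summary reports rankings, fold ratios and lowest tallies", {
  means <- mock11_yield_means()
  ys <- yield_summary(means)
  expect_equal(ys$per_sample$Staphylococcus_aureus$top_method, "method4")
  expect_equal(ys$per_sample$Staphylococcus_aureus$fold_ratio_1dp, 5.7)
  expect_equal(ys$per_sample$Propionibacterium_acnes$fold_ratio_1dp, 5.4)
  expect_equal(
    ys$per_sample$Corynebacterium_tuberculostearicum$fold_ratio_1dp, 3.3)
  expect_equal(unname(ys$lowest_counts["method3"]), 7L)
  expect_equal(ys$n_samples, 12)

  # ties are reported and give fold ratio 1
  tied <- data.frame(method = c("a", "b"), sample = "s",
                     concentration = c(2, 2))
  yst <- yield_summary(tied)
  expect_equal(yst$per_sample$s$fold_ratio, 1)
  expect_equal(yst$per_sample$s$ties, c("a", "b"))

  # missing cells are refused
  expect_error(yield_summary(means[-1, ]), "missing")
})

test_that("yield tables round-trip through TSV", {
  yt <- sim_yield_table(methods = 2, samples = 2, reps = 2, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_yield_table(yt, path)
  back <- read_yield_table(path)
  expect_equal(back$concentration, yt$concentration)
  expect_equal(back$method, yt$method)
})
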