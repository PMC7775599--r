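# reference values computed once with an independent implementation of the
# same published z-transformations (scipy.stats.normaltest / skewtest /
# kurtosistest) on the frozen fixtures below
test_that("D'Agostino-Pearson omnibus matches frozen reference values", {
  x1 <- c(4.347927, 6.104924, 3.650112, 5.428719, 5.621538, 7.347933,
          6.237580, 4.774531, 6.834057, 4.553481, 6.052896, 3.410311,
          7.855511, 2.066361, 4.526633, 4.613324, 3.300491, 5.116931,
          3.364659, 0.899384)
  r <- dagostino_pearson(x1)
  expect_equal(r$statistic, 0.6180075957051877, tolerance = 1e-10)
  expect_equal(r$p_value, 0.7341779817212164, tolerance = 1e-10)
  expect_equal(r$z_skew, -0.6896949326298971, tolerance = 1e-10)
  expect_equal(r$z_kurt, 0.37726449025826614, tolerance = 1e-10)

  x2 <- c(1.999112, 2.049985, 2.541152, 2.871858, 1.086774, 4.268695,
          0.719097, 0.937425, 2.328747, 0.074815, 0.763223, 0.353103,
          1.258359, 1.240180, 0.439744, 0.026452, 1.826936, 0.324972,
          0.785616, 1.285205, 1.626077, 6.572450, 3.705693, 0.741040,
          1.103212)
  r <- dagostino_pearson(x2)
  expect_equal(r$statistic, 18.485560103554768, tolerance = 1e-10)
  expect_equal(r$p_value, 9.680808428990439e-05, tolerance = 1e-10)

  x3 <- c(0.758214, -2.319327, -0.459505, -1.105384, 0.402928, 0.568935,
          -0.706083, -0.290091, -1.483878, -1.150255, -0.274471, 0.577901,
          -1.396903, 0.749058, -1.051187, 8, 9, 10)
  r <- dagostino_pearson(x3)
  expect_equal(r$statistic, 11.18411409396749, tolerance = 1e-10)
  expect_equal(r$z_kurt, 1.5646551840333502, tolerance = 1e-10)

  expect_error(dagostino_pearson(rnorm(7)), "n >= 8")
})

test_that("two-group comparison gates on normality and picks the right test", {
  set.seed(51)
  a <- rnorm(60, 0, 1); b <- rnorm(60, 1, 1)   # effect size d = 1
  r <- compare_two_groups(list(ctrl = a, trt = b))
  expect_match(r$test_name, "t-test")
  expect_true(r$normal_branch)
  expect_lt(r$p_value, 0.05)
  # statistic agrees with a direct pooled-variance t computation
  sp <- sqrt(((59) * var(a) + (59) * var(b)) / 118)
  t_direct <- (mean(a) - mean(b)) / (sp * sqrt(1 / 60 + 1 / 60))
  expect_equal(r$statistic, t_direct, tolerance = 1e-12)

  sa <- rexp(60)^2; sb <- rexp(60)^2           # heavily skewed
  r <- compare_two_groups(list(ctrl = sa, trt = sb))
  expect_match(r$test_name, "Mann-Whitney")
  expect_false(r$normal_branch)
  # statistic agrees with the rank-sum U computed from first principles
  rk <- rank(c(sa, sb))
  u <- sum(rk[1:60]) - 60 * 61 / 2
  expect_equal(unname(r$statistic), u)

  # gate outcome is a pure function of the data
  r2 <- compare_two_groups(list(ctrl = sa, trt = sb))
  expect_identical(r$normality_p, r2$normality_p)

  expect_error(compare_two_groups(list(a = rnorm(5), b = rnorm(20))),
               "n < 8")
  expect_error(compare_two_groups(list(a = 1:10)), "two groups")
})

test_that("group summaries report mean and SEM = SD/sqrt(n)", {
  set.seed(52)
  a <- rnorm(20); b <- rnorm(20)
  r <- compare_two_groups(list(a = a, b = b))
  expect_equal(r$group_summaries$mean[1], mean(a))
  expect_equal(r$group_summaries$sem[1], sd(a) / sqrt(20))
  expect_equal(r$group_summaries$n, c(20L, 20L))
})

test_that("undefined endpoint values are dropped with effective n reported", {
  set.seed(53)
  a <- c(rnorm(20), NA, NA); b <- rnorm(20)
  r <- compare_two_groups(list(a = a, b = b))
  expect_equal(r$group_summaries$n[1], 20L)
})

test_that("three-group comparison: omnibus, post hoc and branch choice", {
  set.seed(54)
  g <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30, 2))
  r <- compare_three_groups(g)
  expect_match(r$test_name, "ANOVA")
  expect_equal(nrow(r$posthoc), 3L)
  # Bonferroni adjustment is min(1, 3 * raw p)
  expect_equal(r$posthoc$p_adj, pmin(1, r$posthoc$p_raw * 3))
  sk <- list(a = rexp(30)^2, b = rexp(30)^2, c = rexp(30)^2)
  r <- compare_three_groups(sk)
  expect_match(r$test_name, "Kruskal-Wallis")
  expect_equal(nrow(r$posthoc), 3L)
  expect_error(compare_three_groups(g[1:2]), "three groups")
})

test_that("a single shifted group is flagged by post hoc, the null pair not", {
  set.seed(55)
  hits <- 0
  for (rep in 1:30) {
    g <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30, 1.5))
    r <- compare_three_groups(g)
    ph <- r$posthoc
    sig <- ph$p_adj < 0.05
    shifted <- grepl("c", ph$pair)
    if (all(sig[shifted]) && !any(sig[!shifted])) hits <- hits + 1
  }
  expect_gte(hits / 30, 0.9)
})

test_that("Dunn z statistics match a first-principles mean-rank computation", {
  set.seed(56)
  vals <- c(rexp(12), rexp(10, 0.5), rexp(11, 2))
  grp <- rep(c("a", "b", "c"), c(12, 10, 11))
  d <- dunn_test(vals, grp)
  n <- length(vals); rk <- rank(vals)
  mr <- tapply(rk, grp, mean); ni <- table(grp)
  z_ab <- (mr["a"] - mr["b"]) /
    sqrt(n * (n + 1) / 12 * (1 / ni[["a"]] + 1 / ni[["b"]]))
  expect_equal(d$z[d$pair == "a vs b"], unname(z_ab), tolerance = 1e-12)
  expect_equal(d$p_adj, pmin(1, d$p_raw * 3))
})

test_that("factorial ANOVA reports type III effects with error df N - 4", {
  set.seed(57)
  ns <- c(32, 31, 32, 32)
  toxin <- rep(c("control", "MPP+", "control", "MPP+"), ns)
  treat <- rep(c("none", "none", "PBA", "PBA"), ns)
  y <- rnorm(sum(ns)) + (toxin == "MPP+") * 1.0
  r <- compare_factorial(y, toxin, treat)
  expect_equal(unique(r$anova_table$df_error), 123)
  expect_equal(nrow(r$posthoc), 6L)             # Tukey over 4 cells
  tox_row <- r$anova_table[r$anova_table$effect == "toxin", ]
  expect_lt(tox_row$p, 0.001)

  # identical values in every cell: between-cell F vanishes
  y0 <- rep(c(1, 2, 3), 4)
  r0 <- compare_factorial(y0, rep(c("a", "b"), each = 6),
                          rep(rep(c("x", "y"), each = 3), 2))
  expect_true(all(abs(r0$anova_table$F) < 1e-12))

  expect_error(
    compare_factorial(rnorm(20), rep(c("a", "b"), each = 10),
                      c(rep("x", 15), rep("y", 5))),
    "empty design cell")
})

test_that("injected main effects land on the right factor on average", {
  set.seed(58)
  fs <- replicate(20, {
    toxin <- rep(c("c", "m"), each = 40)
    treat <- rep(rep(c("n", "p"), each = 20), 2)
    y <- rnorm(80) + (toxin == "m") * 1.2
    r <- compare_factorial(y, toxin, treat)
    r$anova_table$F
  })
  expect_gt(mean(fs[1, ]), 10)     # toxin effect
  expect_lt(mean(fs[2, ]), 3)      # treatment near null
  expect_lt(mean(fs[3, ]), 3)      # interaction near null
})
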