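#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino (1970) transformed-skewness z and the
#' Anscombe-Glynn (1983) transformed-kurtosis z into the omnibus statistic
#' `K2 = z_skew^2 + z_kurt^2`, referred to a chi-squared distribution with
#' 2 df. Requires `n >= 8` (the kurtosis transformation degenerates below
#' that).
#'
#' @param x numeric vector (NAs dropped).
#' @return list with `statistic` (K2), `p_value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8L)
    stop("D'Agostino-Pearson omnibus normality test requires n >= 8 (got n = ",
         n, ")", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 == 0) stop("normality test undefined for constant data", call. = FALSE)

  # transformed skewness (D'Agostino 1970)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  if (y == 0) y <- 1
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # transformed kurtosis (Anscombe & Glynn 1983)
  g2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (g2 - eb2) / sqrt(vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  denom <- 1 + xs * sqrt(2 / (a - 4))
  term2 <- sign(denom) * abs((1 - 2 / a) / abs(denom))^(1 / 3)
  z2 <- (1 - 2 / (9 * a) - term2) / sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on pooled mean ranks with tie correction,
#' two-sided, with Bonferroni adjustment over all pairs (the convention of
#' common analysis software).
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length.
#' @return data.frame `pair, z, p_raw, p_adj`.
#' @export
dunn_test <- function(values, groups) {
  groups <- as.factor(groups)
  keep <- !is.na(values)
  values <- values[keep]; groups <- droplevels(groups[keep])
  n <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- tapply(rk, groups, mean)
  ni <- tapply(rk, groups, length)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni[p[1]] + 1 / ni[p[2]]))
    (rbar[p[1]] - rbar[p[2]]) / se
  })
  p_raw <- 2 * pnorm(abs(z), lower.tail = FALSE)
  data.frame(pair = paste(pairs[1, ], pairs[2, ], sep = " vs "),
             z = as.numeric(z), p_raw = p_raw,
             p_adj = pmin(1, p_raw * ncol(pairs)), row.names = NULL)
}

group_summaries <- function(values_by_group) {
  data.frame(
    group = names(values_by_group),
    n = vapply(values_by_group, length, integer(1)),
    mean = vapply(values_by_group, mean, numeric(1)),
    sem = vapply(values_by_group, function(v) sd(v) / sqrt(length(v)),
                 numeric(1)),
    row.names = NULL)
}

drop_undefined <- function(values_by_group) {
  lapply(values_by_group, function(v) v[!is.na(v)])
}

check_gate_n <- function(values_by_group) {
  ns <- vapply(values_by_group, length, integer(1))
  if (any(ns < 8L))
    stop("group(s) ", paste(names(values_by_group)[ns < 8L], collapse = ", "),
         " have n < 8; the D'Agostino-Pearson omnibus normality gate needs ",
         "at least 8 observations per group", call. = FALSE)
}

new_comparison_result <- function(endpoint, design, test_name, statistic,
                                  p_value, summaries, normality_p,
                                  normal_branch, posthoc = NULL,
                                  anova_table = NULL) {
  structure(list(endpoint = endpoint, design = design, test_name = test_name,
                 statistic = statistic, p_value = p_value,
                 group_summaries = summaries, normality_p = normality_p,
                 normal_branch = normal_branch, posthoc = posthoc,
                 anova_table = anova_table),
            class = "comparison_result")
}

#' Two-group comparison with normality-gated test choice
#'
#' Each group is tested for normality with the D'Agostino-Pearson omnibus
#' test; when both pass (p > alpha) the groups are compared with a
#' two-tailed unpaired t-test, otherwise with a two-tailed Mann-Whitney U
#' test (the nonparametric branch is taken whenever any group fails the
#' gate). Undefined endpoint values (`NA`, e.g. bout duration of a larva
#' that never moved) are dropped per group, and the effective n reported.
#'
#' @param values_by_group named list of two numeric vectors.
#' @param alpha significance (and normality-gate) level.
#' @param endpoint endpoint name carried into the result.
#' @return a `comparison_result`.
#' @export
compare_two_groups <- function(values_by_group, alpha = 0.05,
                               endpoint = NA_character_) {
  if (length(values_by_group) != 2L)
    stop("exactly two groups required", call. = FALSE)
  g <- drop_undefined(values_by_group)
  check_gate_n(g)
  norm_p <- vapply(g, function(v) dagostino_pearson(v)$p_value, numeric(1))
  normal <- all(norm_p > alpha)
  if (normal) {
    tst <- t.test(g[[1]], g[[2]], var.equal = TRUE)
    nm <- "two-tailed unpaired t-test"
  } else {
    tst <- suppressWarnings(wilcox.test(g[[1]], g[[2]]))
    nm <- "two-tailed Mann-Whitney U test"
  }
  new_comparison_result(endpoint, "two_group", nm,
                        unname(tst$statistic), tst$p.value,
                        group_summaries(g), norm_p, normal)
}

#' Three-group comparison: omnibus plus post hoc
#'
#' Normality gate over all three groups: if all pass, one-way ANOVA with
#' Bonferroni-adjusted pairwise t-tests (pooled SD); otherwise
#' Kruskal-Wallis with Dunn's post hoc test. All pairwise comparisons are
#' reported with adjusted p-values.
#'
#' @inheritParams compare_two_groups
#' @param values_by_group named list of three numeric vectors.
#' @return a `comparison_result` with a `posthoc` data.frame.
#' @export
compare_three_groups <- function(values_by_group, alpha = 0.05,
                                 endpoint = NA_character_) {
  if (length(values_by_group) != 3L)
    stop("exactly three groups required", call. = FALSE)
  g <- drop_undefined(values_by_group)
  check_gate_n(g)
  norm_p <- vapply(g, function(v) dagostino_pearson(v)$p_value, numeric(1))
  normal <- all(norm_p > alpha)
  values <- unlist(g, use.names = FALSE)
  grp <- factor(rep(names(g), lengths(g)), levels = names(g))
  if (normal) {
    fit <- aov(values ~ grp)
    sm <- summary(fit)[[1]]
    stat <- sm$`F value`[1]; p <- sm$`Pr(>F)`[1]
    nm <- "one-way ANOVA"
    pw <- stats::pairwise.t.test(values, grp, p.adjust.method = "none",
                                 pool.sd = TRUE)$p.value
    pairs <- utils::combn(levels(grp), 2)
    p_raw <- apply(pairs, 2, function(pr) {
      pv <- pw[pr[2], pr[1]]
      if (is.na(pv)) pw[pr[1], pr[2]] else pv
    })
    posthoc <- data.frame(pair = paste(pairs[1, ], pairs[2, ], sep = " vs "),
                          p_raw = p_raw,
                          p_adj = pmin(1, p_raw * ncol(pairs)),
                          row.names = NULL)
    posthoc_name <- "Bonferroni"
  } else {
    tst <- kruskal.test(values, grp)
    stat <- unname(tst$statistic); p <- tst$p.value
    nm <- "Kruskal-Wallis"
    posthoc <- dunn_test(values, grp)
    posthoc_name <- "Dunn"
  }
  res <- new_comparison_result(endpoint, "three_group",
                               paste(nm, "+", posthoc_name, "post hoc"),
                               stat, p, group_summaries(g), norm_p, normal,
                               posthoc = posthoc)
  res
}

#' 2x2 factorial comparison: two-way ANOVA plus Tukey post hoc
#'
#' Fits `value ~ toxin * treatment` and reports type III F tests for both
#' main effects and the interaction (sum-to-zero contrasts, the convention
#' of common analysis software for unbalanced factorial designs), with
#' Tukey HSD over the four design cells. The error df is `N - 4`.
#'
#' @param values numeric endpoint vector (NAs dropped).
#' @param toxin,treatment factors of the same length (two levels each).
#' @param alpha significance level.
#' @param endpoint endpoint name carried into the result.
#' @return a `comparison_result`; `anova_table` holds one row per effect
#'   (`F`, `df`, `df_error`, `p`), `posthoc` the Tukey cell contrasts, and
#'   `statistic`/`p_value` the interaction test.
#' @export
compare_factorial <- function(values, toxin, treatment, alpha = 0.05,
                              endpoint = NA_character_) {
  keep <- !is.na(values)
  values <- values[keep]
  toxin <- droplevels(as.factor(toxin[keep]))
  treatment <- droplevels(as.factor(treatment[keep]))
  if (nlevels(toxin) != 2L || nlevels(treatment) != 2L ||
      any(table(toxin, treatment) == 0L))
    stop("empty design cell in 2x2 factorial", call. = FALSE)
  n <- length(values)
  d <- data.frame(values = values, toxin = toxin, treatment = treatment)
  fit <- aov(values ~ toxin * treatment, data = d,
             contrasts = list(toxin = "contr.sum", treatment = "contr.sum"))
  a3 <- car::Anova(fit, type = 3)
  eff <- c("toxin", "treatment", "toxin:treatment")
  df_err <- a3[["Df"]][rownames(a3) == "Residuals"]
  tab <- data.frame(effect = eff,
                    F = a3[eff, "F value"],
                    df = a3[eff, "Df"],
                    df_error = df_err,
                    p = a3[eff, "Pr(>F)"], row.names = NULL)
  cell <- interaction(toxin, treatment, sep = ":")
  tk <- TukeyHSD(aov(values ~ cell, data = data.frame(values, cell)))$cell
  posthoc <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                        p_adj = tk[, "p adj"], row.names = NULL)
  cells <- split(values, cell)
  res <- new_comparison_result(
    endpoint, "factorial_2x2",
    "two-way ANOVA (type III) + Tukey post hoc",
    tab$F[tab$effect == "toxin:treatment"],
    tab$p[tab$effect == "toxin:treatment"],
    group_summaries(cells), normality_p = NULL, normal_branch = NA,
    posthoc = posthoc, anova_table = tab)
  res
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Comparison (%s)%s: %s\n", x$design,
              if (is.na(x$endpoint)) "" else paste0(" of ", x$endpoint),
              x$test_name))
  if (!is.null(x$normality_p))
    cat("  normality gate p:",
        paste(sprintf("%.3g", x$normality_p), collapse = ", "),
        if (isTRUE(x$normal_branch)) "(parametric branch)"
        else "(nonparametric branch)", "\n")
  cat(sprintf("  statistic = %.4g, p = %.4g\n", x$statistic, x$p_value))
  s <- x$group_summaries
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-18s n = %3d  mean = %.4g +/- %.3g SEM\n",
                s$group[i], s$n[i], s$mean[i], s$sem[i]))
  if (!is.null(x$anova_table)) {
    cat("  effects:\n")
    a <- x$anova_table
    for (i in seq_len(nrow(a)))
      cat(sprintf("    %-16s F(%d,%d) = %.3f, p = %.4g\n",
                  a$effect[i], a$df[i], a$df_error[i], a$F[i], a$p[i]))
  }
  if (!is.null(x$posthoc)) {
    cat("  post hoc (adjusted p):\n")
    for (i in seq_len(nrow(x$posthoc)))
      cat(sprintf("    %-28s p = %.4g\n", x$posthoc$pair[i],
                  x$posthoc$p_adj[i]))
  }
  invisible(x)
}
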