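# Cohort statistics: normality-gated two-sample and paired comparisons,
# summary-statistic t-tests, Benjamini-Hochberg FDR adjustment and
# Spearman correlation. All p-values are two-sided; the working
# significance level is 0.05.

stats_row <- function(comparison, test, statistic, df, p_value,
                      n1 = NA_integer_, n2 = NA_integer_) {
  tibble::tibble(
    comparison = comparison, test = test,
    statistic = statistic, df = df, p_value = p_value,
    n1 = n1, n2 = n2
  )
}

#' Shapiro-Wilk normality gate
#'
#' Classifies a sample as `"normal"` when the Shapiro-Wilk p-value is at
#' least `alpha`; the gate selects between parametric and rank-based
#' branches of the comparison functions. A zero-variance sample cannot be
#' tested and is flagged `"non-normal"` with a warning.
#'
#' @param x Numeric sample, `n >= 3`.
#' @param alpha Gate level (default 0.05).
#' @return `"normal"` or `"non-normal"`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3L) {
    stop("normality gate needs at least 3 observations, got ", length(x))
  }
  if (stats::sd(x) == 0) {
    warning("zero-variance sample: normality undefined, treated as non-normal")
    return("non-normal")
  }
  p <- stats::shapiro.test(x)$p.value
  if (p >= alpha) "normal" else "non-normal"
}

use_exact_rank_test <- function(...) {
  samples <- list(...)
  all(lengths(samples) <= 20L) &&
    !anyDuplicated(unlist(samples))
}

#' Two-sample comparison with a normality gate
#'
#' `method = "auto"` runs a pooled-variance (Student) t-test when both
#' samples pass the Shapiro-Wilk gate and a Mann-Whitney U test otherwise.
#' The Mann-Whitney branch uses the exact null distribution for small
#' untied samples (both n <= 20) and the tie-corrected normal
#' approximation above that. Degenerate edge: two identical constant
#' samples give p = 1; constant samples with different values give p = 0.
#'
#' @param x,y Numeric samples, each `n >= 2`.
#' @param method `"auto"`, `"pooled_t"` or `"mann_whitney"`.
#' @param comparison Label carried into the result.
#' @param alpha Normality-gate level.
#' @return One-row tibble: `comparison`, `test`, `statistic`, `df`,
#'   `p_value`, `n1`, `n2`.
#' @export
two_sample_test <- function(x, y, method = c("auto", "pooled_t",
                                             "mann_whitney"),
                            comparison = "x vs y", alpha = 0.05) {
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs at least 2 observations")
  }
  if (method == "auto") {
    method <- if (normality_gate(x, alpha) == "normal" &&
                  normality_gate(y, alpha) == "normal") {
      "pooled_t"
    } else {
      "mann_whitney"
    }
  }
  if (method == "pooled_t") {
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
      return(stats_row(comparison, "pooled t",
                       if (p == 1) 0 else Inf,
                       length(x) + length(y) - 2, p,
                       length(x), length(y)))
    }
    tt <- stats::t.test(x, y, var.equal = TRUE)
    stats_row(comparison, "pooled t", unname(tt$statistic),
              unname(tt$parameter), tt$p.value, length(x), length(y))
  } else {
    exact <- use_exact_rank_test(x, y)
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = !exact)
    )
    stats_row(comparison, "Mann-Whitney U", unname(wt$statistic),
              NA_real_, wt$p.value, length(x), length(y))
  }
}

#' Pooled two-sample t-test from summary statistics
#'
#' Recomputes the unpaired comparison from published mean/SD/n triples:
#' `s_p^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2)`,
#' `t = (mean1-mean2) / (s_p sqrt(1/n1 + 1/n2))`, `df = n1+n2-2`,
#' two-sided p. A Welch variant is available for unequal variances.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries; SDs must be positive
#'   and each n at least 2.
#' @param comparison Label carried into the result.
#' @param welch Use the Welch-Satterthwaite form instead of pooling.
#' @return One-row tibble as in [two_sample_test()].
#' @export
#' @examples
#' summary_ttest(1.003, 0.108, 15, 1.263, 0.161, 8)
summary_ttest <- function(mean1, sd1, n1, mean2, sd2, n2,
                          comparison = "group1 vs group2", welch = FALSE) {
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
    label <- "Welch t"
  } else {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    t <- (mean1 - mean2) / (sqrt(sp2) * sqrt(1 / n1 + 1 / n2))
    label <- "pooled t"
  }
  p <- 2 * stats::pt(-abs(t), df)
  stats_row(comparison, label, t, df, p, as.integer(n1), as.integer(n2))
}

#' Paired comparison with a normality gate
#'
#' `method = "auto"` applies a paired t-test when the within-pair
#' differences pass the Shapiro-Wilk gate and a Wilcoxon signed-rank test
#' otherwise. The signed-rank branch uses the exact null for small
#' samples without ties among the non-zero absolute differences;
#' zero differences are dropped before ranking (Wilcoxon's original
#' treatment). All-zero differences give p = 1 with a warning.
#'
#' @param pre,post Paired numeric vectors of equal length.
#' @param method `"auto"`, `"paired_t"` or `"wilcoxon"`.
#' @param comparison Label carried into the result.
#' @param alpha Normality-gate level.
#' @return One-row tibble as in [two_sample_test()].
#' @export
paired_test <- function(pre, post, method = c("auto", "paired_t",
                                              "wilcoxon"),
                        comparison = "pre vs post", alpha = 0.05) {
  method <- match.arg(method)
  if (length(pre) != length(post)) stop("paired samples differ in length")
  keep <- !(is.na(pre) | is.na(post))
  pre <- pre[keep]; post <- post[keep]
  if (length(pre) < 2L) stop("need at least 2 complete pairs")
  d <- post - pre
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(stats_row(comparison, "paired t", 0, length(d) - 1, 1,
                     length(d), length(d)))
  }
  if (method == "auto") {
    method <- if (normality_gate(d, alpha) == "normal") {
      "paired_t"
    } else {
      "wilcoxon"
    }
  }
  if (method == "paired_t") {
    tt <- stats::t.test(post, pre, paired = TRUE)
    stats_row(comparison, "paired t", unname(tt$statistic),
              unname(tt$parameter), tt$p.value, length(pre), length(post))
  } else {
    dz <- d[d != 0]
    exact <- length(dz) <= 25L && !anyDuplicated(abs(dz))
    wt <- suppressWarnings(
      stats::wilcox.test(dz, exact = exact, correct = !exact)
    )
    stats_row(comparison, "Wilcoxon signed-rank", unname(wt$statistic),
              NA_real_, wt$p.value, length(pre), length(post))
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment over one family of tests: with the raw p-values
#' sorted ascending, `adj_(i) = min_{j >= i} (m * p_(j) / j)` capped at 1,
#' returned in the input order. Adjusted values are never below the raw
#' ones and are monotone along the sorted raw p-values.
#'
#' @param pvals Numeric vector of raw p-values in `[0, 1]`.
#' @return Vector of adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Spearman rank correlation
#'
#' Midranks handle ties; the p-value uses the exact permutation null for
#' small untied samples (n <= 9) and the t approximation otherwise.
#'
#' @param x,y Paired numeric vectors, `n >= 3` complete pairs.
#' @param comparison Label carried into the result.
#' @return One-row tibble with `comparison`, `rho`, `p_value`, `n`.
#' @export
spearman_corr <- function(x, y, comparison = "x vs y") {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("Spearman correlation needs at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: Spearman correlation undefined")
  }
  exact <- n <= 9L && !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact)
  )
  tibble::tibble(comparison = comparison,
                 rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Baseline pairwise group comparisons with FDR adjustment
#'
#' Runs the three pairwise baseline comparisons (R vs HC, NR vs HC,
#' R vs NR) on a cohort table and adjusts them as one Benjamini-Hochberg
#' family — the family structure under which the published adjusted
#' p-values are reproducible.
#'
#' @param cohort Tibble with `group`, `timepoint`, `alps_index`.
#' @param timepoint Timepoint analysed (default `"t0"`).
#' @param method Passed to [two_sample_test()].
#' @param value Column tested (default `"alps_index"`).
#' @return Tibble of the three comparisons with `p_adjusted` and a
#'   `family` label appended.
#' @export
baseline_group_tests <- function(cohort, timepoint = "t0", method = "auto",
                                 value = "alps_index") {
  tp <- cohort[cohort$timepoint == timepoint, ]
  pull_group <- function(g) tp[[value]][tp$group == g]
  pairs <- list(c("R", "HC"), c("NR", "HC"), c("R", "NR"))
  res <- purrr::map_dfr(pairs, function(pr) {
    two_sample_test(pull_group(pr[1]), pull_group(pr[2]), method = method,
                    comparison = paste(pr[1], "vs", pr[2]))
  })
  res$p_adjusted <- bh_adjust(res$p_value)
  res$family <- paste0("baseline_", timepoint)
  res
}

#' Baseline pairwise comparisons recomputed from published summaries
#'
#' Applies [summary_ttest()] to per-group mean/SD/n rows at one timepoint
#' and BH-adjusts the three pairwise comparisons as one family.
#'
#' @param summaries Tibble like [alps_reference_summaries()].
#' @param timepoint Timepoint analysed (default `"t0"`).
#' @return Tibble of the three comparisons with `p_adjusted`.
#' @export
summary_group_tests <- function(summaries = alps_reference_summaries(),
                                timepoint = "t0") {
  tp <- summaries[summaries$timepoint == timepoint, ]
  if (nrow(tp) != 3L) {
    stop("expected exactly 3 groups at timepoint ", timepoint,
         ", found ", nrow(tp))
  }
  pairs <- list(c("R", "HC"), c("NR", "HC"), c("R", "NR"))
  res <- purrr::map_dfr(pairs, function(pr) {
    a <- tp[tp$group == pr[1], ]; b <- tp[tp$group == pr[2], ]
    summary_ttest(a$mean, a$sd, a$n, b$mean, b$sd, b$n,
                  comparison = paste(pr[1], "vs", pr[2]))
  })
  res$p_adjusted <- bh_adjust(res$p_value)
  res$family <- paste0("baseline_", timepoint)
  res
}

#' Within-group longitudinal comparisons
#'
#' Paired comparisons of the ALPS index between baseline and each later
#' timepoint within every group that has follow-up data, matched by
#' subject; each group's set of within-group tests forms one BH family.
#'
#' @param cohort Tibble with `subject_id`, `group`, `timepoint`,
#'   `alps_index`.
#' @param method Passed to [paired_test()].
#' @return Tibble of paired comparisons with `p_adjusted`.
#' @export
longitudinal_group_tests <- function(cohort, method = "auto") {
  wide <- tidyr::pivot_wider(
    cohort[, c("subject_id", "group", "timepoint", "alps_index")],
    names_from = "timepoint", values_from = "alps_index"
  )
  res <- purrr::map_dfr(unique(wide$group), function(g) {
    wg <- wide[wide$group == g, ]
    tps <- setdiff(intersect(c("t1_postTT", "t3_postVPS"), names(wg)), NA)
    purrr::map_dfr(tps, function(tp) {
      keep <- !is.na(wg$t0) & !is.na(wg[[tp]])
      if (sum(keep) < 3L) return(NULL)
      out <- paired_test(wg$t0[keep], wg[[tp]][keep], method = method,
                         comparison = paste(g, ": t0 vs ", tp, sep = ""))
      out$group <- g
      out
    }) -> gres
    if (is.null(gres) || !nrow(gres)) return(NULL)
    gres$p_adjusted <- bh_adjust(gres$p_value)
    gres$family <- paste0("within_", g)
    gres
  })
  res
}

#' Correlate the ALPS index with radiological covariates
#'
#' Spearman correlations between the baseline ALPS index and each
#' available covariate column (e.g. Evans index, callosal angle,
#' Radscale).
#'
#' @param cohort Tibble with `timepoint`, `alps_index` and covariate
#'   columns.
#' @param covariates Character vector of covariate column names; defaults
#'   to those present among `evans_index`, `callosal_angle_deg`,
#'   `radscale`.
#' @param timepoint Timepoint analysed.
#' @return Tibble of correlations, one row per covariate.
#' @export
covariate_correlations <- function(cohort,
                                   covariates = intersect(
                                     c("evans_index", "callosal_angle_deg",
                                       "radscale"), names(cohort)),
                                   timepoint = "t0") {
  tp <- cohort[cohort$timepoint == timepoint, ]
  purrr::map_dfr(covariates, function(cv) {
    spearman_corr(tp[[cv]], tp$alps_index,
                  comparison = paste("alps_index vs", cv))
  })
}
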