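# group-level inference, both from raw values and from printed summaries

#' Group summary (mean, SD, N)
#'
#' @param values Numeric vector (n >= 2 for a finite SD).
#' @return An object of class `group_summary` with `mean`, `sd` (n-1
#'   denominator), `n`.
#' @export
summarize_group <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 1L) stop_data("no finite values to summarize")
  structure(list(mean = mean(values), sd = stats::sd(values),
                 n = length(values)),
            class = "group_summary")
}

#' Construct a group summary from printed numbers
#'
#' @param mean,sd,n The printed mean, SD and group size.
#' @return A `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  if (n < 2) stop_invalid("group size must be >= 2")
  if (sd < 0) stop_invalid("sd must be >= 0")
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %.4g ± %.4g (n = %d)\n", x$mean, x$sd, x$n))
  invisible(x)
}

.test_result <- function(statistic, p, df, method) {
  structure(list(statistic = unname(statistic), p = unname(p),
                 df = unname(df), method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, df = %s, p = %.4g\n",
              x$method, x$statistic, paste(signif(x$df, 5), collapse = ", "),
              x$p))
  invisible(x)
}

#' One-way ANOVA on raw per-group values
#'
#' Classic fixed-effects F test via [stats::aov()].
#'
#' @param groups List of numeric vectors, one per group.
#' @return A `test_result` (F statistic, `(df_between, df_within)`, p).
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2L) stop_data("need at least 2 groups")
  d <- data.frame(y = unlist(groups),
                  g = factor(rep(seq_along(groups), lengths(groups))))
  tab <- stats::anova(stats::aov(y ~ g, data = d))
  f <- tab[["F value"]][1]
  if (!is.finite(f)) f <- 0            # zero between-group variance
  p <- tab[["Pr(>F)"]][1]
  if (!is.finite(p)) p <- 1
  .test_result(f, p, c(tab$Df[1], tab$Df[2]), "one-way ANOVA")
}

#' One-way ANOVA from printed (mean, SD, N) summaries
#'
#' Algebraically identical to [anova_oneway()] on any data set having
#' exactly those group summaries: the between-group sum of squares comes
#' from the means and sizes, the within-group sum of squares from the SDs.
#' This makes published "mean ± SD, N" tables re-testable.
#'
#' @param summaries List of `group_summary` objects (>= 2).
#' @return A `test_result`.
#' @export
anova_from_summary <- function(summaries) {
  stopifnot(all(vapply(summaries, inherits, logical(1), "group_summary")))
  if (length(summaries) < 2L) stop_data("need at least 2 groups")
  n <- vapply(summaries, `[[`, numeric(1), "n")
  m <- vapply(summaries, `[[`, numeric(1), "mean")
  s <- vapply(summaries, `[[`, numeric(1), "sd")
  N <- sum(n); k <- length(n)
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * s^2)
  df1 <- k - 1; df2 <- N - k
  if (ssw <= 0) {
    f <- if (ssb <= 0) 0 else Inf
  } else {
    f <- (ssb / df1) / (ssw / df2)
  }
  p <- if (!is.finite(f)) 0 else if (f == 0) 1 else
    stats::pf(f, df1, df2, lower.tail = FALSE)
  .test_result(f, p, c(df1, df2), "one-way ANOVA (from summaries)")
}

#' Welch's t test from two printed (mean, SD, N) summaries
#'
#' Unequal-variance two-sample t test computed from summary statistics,
#' with Welch-Satterthwaite degrees of freedom. Used to re-test published
#' pairwise comparisons for which only "mean ± SD, N" is printed.
#'
#' @param a,b `group_summary` objects.
#' @return A `test_result` (two-sided p).
#' @export
welch_t_from_summary <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
  se <- sqrt(va + vb)
  if (se == 0) return(.test_result(0, 1, Inf, "Welch t (from summaries)"))
  t <- (a$mean - b$mean) / se
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  .test_result(t, p, df, "Welch t (from summaries)")
}

#' Tukey HSD post-hoc pairwise comparisons
#'
#' Studentized-range adjusted pairwise tests after a one-way ANOVA, via
#' [stats::TukeyHSD()].
#'
#' @param groups Named (or unnamed) list of numeric vectors.
#' @return Data frame with one row per pair: `pair`, `diff`, `p_adj`.
#' @export
tukey_hsd <- function(groups) {
  if (length(groups) < 2L) stop_data("need at least 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  d <- data.frame(y = unlist(groups),
                  g = factor(rep(names(groups), lengths(groups)),
                             levels = names(groups)))
  if (stats::var(d$y) == 0) {
    cn <- utils::combn(names(groups), 2)
    return(data.frame(pair = paste(cn[2, ], cn[1, ], sep = "-"),
                      diff = 0, p_adj = 1, stringsAsFactors = FALSE))
  }
  tk <- stats::TukeyHSD(stats::aov(y ~ g, data = d))$g
  data.frame(pair = rownames(tk), diff = tk[, "diff"], p_adj = tk[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pearson chi-square test on two binned distributions
#'
#' Pearson chi-square on the 2 x K contingency table of bin counts (no
#' continuity correction). Bins empty in both histograms are dropped; if a
#' retained bin still yields a zero expected count, adjacent bins are
#' merged (and the merge logged via `message`).
#'
#' @param counts_a,counts_b Integer bin counts over identical bin edges.
#' @return A `test_result` (chi-square statistic, df, p).
#' @export
chi_square_binned <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b))
    stop_invalid("histograms must share bin edges (equal length)")
  keep <- counts_a + counts_b > 0
  a <- counts_a[keep]; b <- counts_b[keep]
  if (length(a) < 2L) stop_data("fewer than 2 informative bins")
  if (sum(a) == 0 || sum(b) == 0) {
    # one distribution entirely empty: expected counts are degenerate
    tot <- a + b
    exp_zero <- any(tot == 0)
    if (exp_zero) message("merging adjacent empty bins")
    stop_data("one histogram has no counts; chi-square undefined")
  }
  tab <- rbind(a, b)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  while (any(expd == 0) && ncol(tab) > 2L) {
    j <- which(colSums(expd) == 0)[1]
    k <- if (j == 1L) 2L else j - 1L
    message(sprintf("merging bin %d into bin %d (zero expected count)", j, k))
    tab[, k] <- tab[, k] + tab[, j]
    tab <- tab[, -j, drop = FALSE]
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  }
  chi <- sum((tab - expd)^2 / expd)
  df <- ncol(tab) - 1
  .test_result(chi, stats::pchisq(chi, df, lower.tail = FALSE), df,
               "Pearson chi-square (binned)")
}

#' Linear regression of PIC amplitude on input conductance
#'
#' Within-group linear fit of the per-cell PIC amplitude against input
#' conductance (the "bigger cells have bigger PICs" relation); its strength
#' distinguishes hypoexcitable cells.
#'
#' @param records Data frame with columns `PIC_amp_pA` and `G_in_nS`
#'   (optionally `group`).
#' @param group Optional group label to filter on.
#' @return List with `slope` (pA/nS), `intercept` (pA), `r` (signed
#'   Pearson correlation), `n`.
#' @export
linreg_pic_vs_gin <- function(records, group = NULL) {
  d <- as.data.frame(records)
  if (!is.null(group)) d <- d[d$group %in% group, ]
  d <- d[is.finite(d$PIC_amp_pA) & is.finite(d$G_in_nS), ]
  if (nrow(d) < 2L) stop_data("need at least 2 cells for the regression")
  fit <- stats::lm(PIC_amp_pA ~ G_in_nS, data = d)
  b <- unname(stats::coef(fit))
  list(slope = b[2], intercept = b[1],
       r = stats::cor(d$G_in_nS, d$PIC_amp_pA), n = nrow(d))
}

#' PIC-to-input-conductance ratio
#'
#' `PIC_amp_pA / G_in_nS`, in mV (signed; inward-negative PICs give
#' negative ratios). A per-cell excitability metric normalizing PIC
#' strength by cell size.
#'
#' @param pic_amp_pA PIC amplitude(s), pA.
#' @param g_in_nS Input conductance(s), nS.
#' @return Ratio in mV. Vectorized.
#' @export
pic_gin_ratio <- function(pic_amp_pA, g_in_nS) {
  if (any(g_in_nS <= 0, na.rm = TRUE)) stop_invalid("G_in must be positive")
  pic_amp_pA / g_in_nS
}

#' Reduction between two percentages, in percentage points
#'
#' @param p_before,p_after Percentages.
#' @return `p_before - p_after` (percentage points).
#' @export
percent_reduction <- function(p_before, p_after) p_before - p_after
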