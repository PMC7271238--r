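# group summaries, ANOVA (raw and from summaries), Welch t, Tukey, chi-square

# reconstruct n values with exactly the given mean and SD
exact_sample <- function(mean, sd, n) {
  z <- stats::rnorm(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}

test_that("summarize_group returns the sample mean/SD/N", {
  s <- summarize_group(c(1, 2, 3))
  expect_equal(c(s$mean, s$sd, s$n), c(2, 1, 3))
  expect_equal(summarize_group(rep(7, 5))$sd, 0)
  # two-pass oracle on many random values
  set.seed(1)
  x <- stats::rnorm(1e6, 50, 12)
  s2 <- summarize_group(x)
  m <- sum(x) / length(x)
  expect_equal(s2$mean, m, tolerance = 1e-9)
  expect_equal(s2$sd, sqrt(sum((x - m)^2) / (length(x) - 1)), tolerance = 1e-9)
})

test_that("one-way ANOVA matches its algebraic identities", {
  expect_equal(anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0)
  expect_equal(anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))$p, 1)
  # two groups: F equals the square of the pooled t statistic
  set.seed(2)
  a <- rnorm(12, 10, 2); b <- rnorm(9, 12, 2)
  f <- anova_oneway(list(a, b))
  t2 <- stats::t.test(a, b, var.equal = TRUE)$statistic^2
  expect_equal(f$statistic, unname(t2), tolerance = 1e-9)
  # agreement with a permutation oracle within Monte-Carlo error
  set.seed(4)
  x <- rnorm(8, 0, 1); y <- rnorm(8, 1.2, 1)
  obs <- anova_oneway(list(x, y))
  pool <- c(x, y)
  perm <- replicate(4000, {
    i <- sample(16, 8)
    anova_oneway(list(pool[i], pool[-i]))$statistic
  })
  p_perm <- mean(perm >= obs$statistic - 1e-12)
  expect_lt(abs(p_perm - obs$p), 3 * sqrt(obs$p * (1 - obs$p) / 4000) + 0.01)
})

test_that("summary-based ANOVA equals raw ANOVA under exact reconstruction", {
  set.seed(5)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    ns <- sample(4:40, k, replace = TRUE)
    ms <- runif(k, -50, 50); ss <- runif(k, 0.5, 20)
    sums <- lapply(seq_len(k), function(j) group_summary(ms[j], ss[j], ns[j]))
    raw <- lapply(seq_len(k), function(j) exact_sample(ms[j], ss[j], ns[j]))
    a1 <- anova_from_summary(sums)
    a2 <- anova_oneway(raw)
    expect_equal(a1$statistic, a2$statistic, tolerance = 1e-9)
    expect_equal(a1$p, a2$p, tolerance = 1e-9)
  }
  expect_equal(anova_from_summary(list(group_summary(5, 2, 10),
                                       group_summary(5, 3, 12)))$statistic, 0)
})

test_that("published soma-volume and PIC summaries re-test as reported", {
  soma <- anova_from_summary(list(group_summary(11812.62, 2653.22, 120),
                                  group_summary(14156.13, 3920.44, 60)))
  expect_lt(soma$p, 0.05)
  expect_lt(welch_t_from_summary(group_summary(-200, 73, 25),
                                 group_summary(-357, 111, 22))$p, 0.01)
  expect_lt(welch_t_from_summary(group_summary(24, 10, 25),
                                 group_summary(32, 10, 22))$p, 0.01)
  expect_lt(welch_t_from_summary(group_summary(-87, 29, 4),
                                 group_summary(-229, 79, 20))$p, 0.01)
  ident <- welch_t_from_summary(group_summary(5, 2, 10), group_summary(5, 2, 10))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p, 1)
})

test_that("Tukey HSD reduces to the pooled t test for two groups", {
  set.seed(6)
  a <- rnorm(10, 0, 1); b <- rnorm(12, 1, 1)
  tk <- tukey_hsd(list(a = a, b = b))
  expect_equal(nrow(tk), 1)
  expect_equal(tk$p_adj, stats::t.test(a, b, var.equal = TRUE)$p.value,
               tolerance = 1e-6)
  # identical groups: all adjusted p = 1
  same <- tukey_hsd(list(g1 = c(1, 2, 3), g2 = c(1, 2, 3), g3 = c(1, 2, 3)))
  expect_true(all(same$p_adj == 1))
  # adjusted p never below the unadjusted pairwise p
  x <- list(a = rnorm(8), b = rnorm(8, 0.5), c = rnorm(8, 1))
  tk3 <- tukey_hsd(x)
  raw_p <- c(stats::t.test(x$b, x$a, var.equal = TRUE)$p.value,
             stats::t.test(x$c, x$a, var.equal = TRUE)$p.value,
             stats::t.test(x$c, x$b, var.equal = TRUE)$p.value)
  expect_true(all(tk3$p_adj >= raw_p - 1e-9))
})

test_that("four-group cohorts flag the WT vs mSOD1 PIC difference", {
  # cohorts at the published PIC presets; Tukey flags WT vs mSOD1 at p < .01
  # in nearly all replicates
  set.seed(7)
  hits <- replicate(100, {
    g <- list(WT = rnorm(25, -200, 73), mSOD1 = rnorm(22, -357, 111),
              WTPF = rnorm(21, -202, 91), mSOD1PF = rnorm(24, -229, 79))
    tk <- tukey_hsd(g)
    tk$p_adj[tk$pair == "mSOD1-WT"] < 0.01
  })
  expect_gte(mean(hits), 0.95)
})

test_that("binned chi-square matches hand computation and Monte Carlo", {
  expect_equal(chi_square_binned(c(5, 10, 5), c(5, 10, 5))$statistic, 0)
  expect_equal(chi_square_binned(c(10, 0), c(0, 10))$statistic, 20)
  expect_equal(chi_square_binned(c(10, 0), c(0, 10))$df, 1)
  # bins empty in both samples are dropped
  expect_equal(chi_square_binned(c(10, 0, 0), c(0, 0, 10))$statistic, 20)
  # Monte-Carlo multinomial oracle on a small fixture
  a <- c(12, 30, 18); b <- c(25, 20, 15)
  obs <- chi_square_binned(a, b)
  set.seed(8)
  pool <- (a + b) / sum(a + b)
  sims <- replicate(2000, {
    aa <- stats::rmultinom(1, sum(a), pool)[, 1]
    bb <- stats::rmultinom(1, sum(b), pool)[, 1]
    suppressMessages(chi_square_binned(aa, bb)$statistic)
  })
  p_mc <- mean(sims >= obs$statistic)
  expect_lt(abs(p_mc - obs$p), 3 * sqrt(obs$p * (1 - obs$p) / 2000) + 0.01)
})

test_that("PIC vs G_in regression and ratio behave as documented", {
  rec <- data.frame(G_in_nS = c(10, 20, 30, 40),
                    PIC_amp_pA = -8 * c(10, 20, 30, 40) - 5)
  lr <- linreg_pic_vs_gin(rec)
  expect_equal(abs(lr$r), 1)
  expect_equal(lr$slope, -8)
  # unit change pA -> nA scales the slope by 1000
  rec_nA <- transform(rec, PIC_amp_pA = PIC_amp_pA / 1000)
  expect_equal(linreg_pic_vs_gin(rec_nA)$slope, -8 / 1000, tolerance = 1e-9)
  expect_equal(pic_gin_ratio(-200, 24), -200 / 24)
  expect_equal(pic_gin_ratio(0, 17), 0)
  expect_equal(pic_gin_ratio(-200, 48), pic_gin_ratio(-200, 24) / 2)
})

test_that("percentage-point reductions match the printed arithmetic", {
  expect_equal(percent_reduction(21, 6.7), 14.3)
  expect_equal(percent_reduction(38.1, 10.5), 27.6)
  expect_equal(percent_reduction(12, 12), 0)
})
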