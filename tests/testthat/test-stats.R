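test_that("two-sample t behaves at the edges and in summary mode", {
  x <- c(1.2, 1.9, 2.4, 3.1)
  got <- two_sample_t(x, x)
  expect_equal(got$t, 0)
  expect_equal(got$p, 1)
  expect_error(two_sample_t(rep(1, 3), rep(1, 3)), "zero variance")

  # pooled row of the published isotope table from its printed summaries
  ts <- t_from_summary(11.3, 0.9, 51, 14.4, 0.8, 62, variant = "pooled")
  expect_equal(ts$df, 111)
  expect_lt(abs(abs(ts$t) / 18.838 - 1), 0.05)
  # welch df formula against stats::t.test on raw data
  withr::with_seed(22, { a <- rnorm(20, 0, 1); b <- rnorm(25, 1, 3) })
  ref <- stats::t.test(a, b)
  got2 <- t_from_summary(mean(a), sd(a), 20, mean(b), sd(b), 25, "welch")
  expect_equal(got2$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got2$df, unname(ref$parameter), tolerance = 1e-12)
})

test_that("Levene test is null on matched spreads and rejects scaled groups", {
  v <- c(1, 2, 3, 11, 12, 13)
  g <- rep(c("a", "b"), each = 3)
  expect_lt(levene_test(v, g)$F, 1e-12)
  withr::with_seed(23, {
    v2 <- c(rnorm(100), rnorm(100) * 5)
  })
  expect_lt(levene_test(v2, rep(c("a", "b"), each = 100))$p, 0.001)
})

test_that("Type III two-way ANOVA matches the balanced textbook decomposition", {
  withr::with_seed(24, y <- rnorm(40, sd = 1))
  a <- rep(c("YS", "BS"), each = 20)
  b <- rep(rep(c("m", "f"), each = 10), 2)
  y <- y + (a == "BS") * 2
  got <- two_way_anova(y, a, b)
  # balanced: Type III equals the classical decomposition
  cell <- tapply(y, list(a, b), mean)
  grand <- mean(y)
  ss_a <- 20 * sum((rowMeans(cell) - grand)^2)
  ss_b <- 20 * sum((colMeans(cell) - grand)^2)
  ss_ab <- 10 * sum((cell - outer(rowMeans(cell), colMeans(cell), "+") + grand)^2)
  ss_err <- sum((y - cell[cbind(a, b)])^2)
  expect_equal(got$F[1], (ss_a / 1) / (ss_err / 36), tolerance = 1e-10)
  expect_equal(got$F[2], (ss_b / 1) / (ss_err / 36), tolerance = 1e-10)
  expect_equal(got$F[3], (ss_ab / 1) / (ss_err / 36), tolerance = 1e-10)
  expect_equal(got$eta_p2[1], ss_a / (ss_a + ss_err), tolerance = 1e-10)

  # constant response flags degenerate
  deg <- two_way_anova(rep(2, 40), a, b)
  expect_true(attr(deg, "degenerate"))
  expect_error(two_way_anova(y[1:20], a[1:20], rep("m", 20)), "cell")
})

test_that("a simulated species shift is detected with a large effect size", {
  withr::with_seed(25, {
    a <- rep(c("YS", "BS"), each = 60)
    b <- sample(rep(c("m", "f"), 60))
    y <- rnorm(120) + (a == "BS") * 2
  })
  got <- two_way_anova(y, a, b)
  expect_lt(got$p[1], 0.001)
  expect_gt(got$eta_p2[1], 0.3)
})

test_that("Wilks MANOVA reduces to univariate ANOVA and flags group effects", {
  withr::with_seed(26, {
    y <- rnorm(63)
    a <- sample(rep(c("YS", "BS"), c(30, 33)))
    b <- sample(rep(c("m", "f"), c(31, 32)))
  })
  uni <- two_way_anova(y, a, b)
  mul <- manova_wilks(matrix(y, ncol = 1), a, b)
  expect_equal(mul$F, uni$F, tolerance = 1e-10)
  expect_equal(mul$p, uni$p, tolerance = 1e-10)

  # strong species effect on many shape-like variables, none for sex
  withr::with_seed(27, {
    n <- 80
    yy <- matrix(rnorm(n * 19, sd = 1), n, 19)
    a2 <- rep(c("YS", "BS"), each = n / 2)
    b2 <- sample(rep(c("m", "f"), n / 2))
    yy[a2 == "BS", 1:5] <- yy[a2 == "BS", 1:5] + 1.5
  })
  got <- manova_wilks(yy, a2, b2)
  expect_lt(got$p[got$effect == "species"], 0.001)
  expect_gt(got$p[got$effect == "sex"], 0.05)
  expect_true(all(got$wilks >= 0 & got$wilks <= 1))
})

test_that("KS normality accepts Gaussian and rejects exponential samples", {
  withr::with_seed(28, xg <- rnorm(1000))
  kg <- ks_normality(xg)
  expect_gt(kg$p_lilliefors, 0.05)
  expect_true(kg$D >= 0 && kg$D <= 1)
  withr::with_seed(29, xe <- rexp(500))
  expect_lt(ks_normality(xe)$p_lilliefors, 0.01)
})

test_that("intra-class correlation tracks the variance ratio", {
  withr::with_seed(30, subj <- rnorm(50, sd = 10))
  m <- cbind(subj, subj)
  expect_equal(icc_consistency(m), 1)
  withr::with_seed(31, noisy <- cbind(subj + rnorm(50), subj + rnorm(50)))
  expect_gt(icc_consistency(noisy), 0.9)
  withr::with_seed(32, indep <- matrix(rnorm(100), 50, 2))
  expect_lt(abs(icc_consistency(indep)), 0.35)
})

test_that("paired t flags degenerate differences and detects offsets", {
  x <- c(1.1, 2.3, 2.9, 4.2)
  got <- paired_t(x, x)
  expect_true(got$degenerate)
  withr::with_seed(33, {
    a <- rnorm(100)
    b <- a + 1 + rnorm(100, sd = 0.5)
  })
  res <- paired_t(a, b)
  expect_lt(res$p, 0.001)
  # equals a one-sample t on the differences
  ref <- stats::t.test(a - b)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
})

test_that("bonferroni threshold divides alpha by the comparison count", {
  expect_equal(bonferroni_threshold(0.05, 4), 0.0125)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 5), 0.002)
})

test_that("REML matches the closed-form balanced one-way estimator", {
  withr::with_seed(34, {
    g <- rep(1:8, each = 12)
    y <- rnorm(8, sd = 2)[g] + rnorm(96)
  })
  av <- stats::anova(stats::aov(y ~ factor(g)))
  closed <- max(0, (av[1, 3] - av[2, 3]) / 12)
  fit <- lme4::lmer(y ~ 1 + (1 | g), REML = TRUE)
  expect_equal(as.data.frame(lme4::VarCorr(fit))$vcov[1], closed,
               tolerance = 1e-6)
})

test_that("variance components separate species, year and error", {
  # no year signal: its share stays small
  withr::with_seed(35, {
    sp <- rep(c("YS", "BS"), each = 120)
    yr <- rep(rep(2001:2006, each = 20), 2)
    y <- (sp == "BS") * 3 + rnorm(240)
  })
  vc <- reml_varcomp(y, sp, yr)
  expect_equal(sum(vc$percent), 100, tolerance = 0.01)
  expect_true(all(vc$components >= 0))
  expect_lt(vc$percent[["year"]], 5)
  expect_gt(vc$percent[["species"]], vc$percent[["year"]])
})

test_that("under default isotope parameters species variance exceeds year variance", {
  co <- simulate_cohort(seed = 36)
  b <- co$birds
  for (v in c("d15N_P1", "d13C_P1", "d13C_R6")) {
    vc <- reml_varcomp(b[[v]], b$true_species, b$moult_year)
    expect_gt(vc$percent[["species"]], vc$percent[["year"]])
  }
})
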