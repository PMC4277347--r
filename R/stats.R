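#' Two-sample t test (pooled or Welch)
#'
#' @param x,y Numeric samples (each `n >= 2`).
#' @param variant `"pooled"` (equal variances, `df = n1 + n2 - 2`) or
#'   `"welch"` (Welch-Satterthwaite df).
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
two_sample_t <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2L || length(y) < 2L) stop_ctx("each sample needs n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop_ctx("zero variance in both samples")
  fit <- stats::t.test(x, y, var.equal = variant == "pooled")
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value))
}

#' Two-sample t test from summary statistics
#'
#' Recomputes the t statistic, degrees of freedom and two-sided p-value
#' from printed group means, SDs and sample sizes (as in a published
#' results table).
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summary statistics.
#' @param variant `"pooled"` or `"welch"`.
#' @return List with `t`, `df`, `p`.
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                           variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Levene's test for homogeneity of variances
#'
#' One-way ANOVA on the absolute deviations from the group means
#' (`car::leveneTest` with `center = mean`).
#'
#' @param values Numeric vector.
#' @param groups Group labels.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
levene_test <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L || any(table(g) < 2L))
    stop_ctx("Levene test needs >= 2 groups with >= 2 observations")
  fit <- car::leveneTest(values, g, center = mean)
  list(F = fit[1, "F value"], df1 = fit[1, "Df"], df2 = fit[2, "Df"],
       p = fit[1, "Pr(>F)"])
}

# Sum-to-zero-contrast lm for Type III sums of squares.
fit_sum_contrasts <- function(formula, data) {
  facs <- names(Filter(is.factor, data))
  contr <- stats::setNames(rep(list("contr.sum"), length(facs)), facs)
  stats::lm(formula, data = data, contrasts = contr)
}

#' Two-way fixed-effects ANOVA with Type III sums of squares
#'
#' `y ~ A * B` with both factors fixed, Type III sums of squares
#' (unbalanced-safe, via `car::Anova`) and partial eta squared
#' `SS_effect / (SS_effect + SS_error)` per effect.
#'
#' @param y Numeric response.
#' @param a,b Factors (two levels each in the study design; more work too).
#' @return A data frame with one row per effect (`a`, `b`, `a:b`): `F`,
#'   `df`, `df_error`, `p`, `eta_p2`; attribute `"degenerate"` set when the
#'   error sum of squares is zero.
#' @export
two_way_anova <- function(y, a, b) {
  dat <- data.frame(y = y, a = factor(a), b = factor(b))
  if (nlevels(dat$a) < 2L || nlevels(dat$b) < 2L ||
      any(table(dat$a, dat$b) == 0L))
    stop_ctx("empty design cell (each factor needs >= 2 populated levels)")
  mod <- fit_sum_contrasts(y ~ a * b, dat)
  n_par <- length(stats::coef(mod))
  ss_err <- sum(stats::residuals(mod)^2)
  if (ss_err < 1e-12 * max(sum(dat$y^2), 1)) {
    out <- data.frame(effect = c("species", "sex", "species:sex"),
                      F = NA_real_, df = c(1L, 1L, 1L),
                      df_error = nrow(dat) - n_par, p = NA_real_,
                      eta_p2 = NA_real_)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  av <- car::Anova(mod, type = 3)
  rows <- c("a", "b", "a:b")
  out <- data.frame(
    effect = c("species", "sex", "species:sex"),
    F = av[rows, "F value"], df = av[rows, "Df"],
    df_error = av["Residuals", "Df"], p = av[rows, "Pr(>F)"],
    eta_p2 = av[rows, "Sum Sq"] / (av[rows, "Sum Sq"] + ss_err))
  attr(out, "degenerate") <- FALSE
  out
}

# Rao's F approximation for Wilks' Lambda.
wilks_to_f <- function(lambda, p, q, v) {
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  m <- v - (p - q + 1) / 2
  df1 <- p * q
  df2 <- m * s - p * q / 2 + 1
  lam_s <- lambda^(1 / s)
  f <- (1 - lam_s) / lam_s * df2 / df1
  list(F = f, df1 = df1, df2 = df2, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       eta_p2 = 1 - lam_s)
}

#' Two-way MANOVA with Wilks' Lambda (Type III)
#'
#' Multivariate `Y ~ A * B`: per effect, `Lambda = det(E) / det(H + E)`
#' with Type III hypothesis SSCP matrices (via `car::Anova`), Rao's F
#' approximation and multivariate partial eta squared
#' `1 - Lambda^(1/s)`.
#'
#' @param y Numeric `n x p` response matrix.
#' @param a,b Factors.
#' @return Data frame with one row per effect: `wilks`, `F`, `df1`, `df2`,
#'   `p`, `eta_p2`.
#' @export
manova_wilks <- function(y, a, b) {
  y <- as.matrix(y)
  dat <- data.frame(a = factor(a), b = factor(b))
  if (nlevels(dat$a) < 2L || nlevels(dat$b) < 2L ||
      any(table(dat$a, dat$b) == 0L))
    stop_ctx("empty design cell (each factor needs >= 2 populated levels)")
  p <- ncol(y)
  n_cells <- nlevels(dat$a) * nlevels(dat$b)
  if (nrow(y) <= p + n_cells)
    stop_ctx("need n > p + number of cells for MANOVA")
  mod <- stats::lm(y ~ a * b, data = dat,
                   contrasts = list(a = "contr.sum", b = "contr.sum"))
  av <- car::Anova(mod, type = 3)
  if (p == 1L) {
    # a 1-column response degenerates to univariate ANOVA: Lambda =
    # SSE / (SSH + SSE) from the Type III sums of squares
    ss_err <- av["Residuals", "Sum Sq"]
    v <- av["Residuals", "Df"]
    if (ss_err < .Machine$double.xmin) stop_ctx("singular error SSCP")
    rows <- lapply(c("a", "b", "a:b"), function(term) {
      h <- av[term, "Sum Sq"]
      q <- av[term, "Df"]
      ap <- wilks_to_f(ss_err / (h + ss_err), p, q, v)
      data.frame(effect = term, wilks = ss_err / (h + ss_err), F = ap$F,
                 df1 = ap$df1, df2 = ap$df2, p = ap$p, eta_p2 = ap$eta_p2)
    })
    out <- do.call(rbind, rows)
    out$effect <- c("species", "sex", "species:sex")
    return(out)
  }
  e <- av$SSPE
  if (abs(det(e)) < .Machine$double.xmin) stop_ctx("singular error SSCP")
  v <- av$error.df
  rows <- lapply(c("a", "b", "a:b"), function(term) {
    h <- av$SSP[[term]]
    q <- av$df[[term]]
    lambda <- det(e) / det(h + e)
    ap <- wilks_to_f(lambda, p, q, v)
    data.frame(effect = term, wilks = lambda, F = ap$F, df1 = ap$df1,
               df2 = ap$df2, p = ap$p, eta_p2 = ap$eta_p2)
  })
  out <- do.call(rbind, rows)
  out$effect <- c("species", "sex", "species:sex")
  out
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic against `Normal(mean(x), sd(x))` with the naive
#' asymptotic p-value, plus the Lilliefors-corrected p-value (which
#' accounts for the estimated parameters).
#'
#' @param x Numeric sample, `n >= 5`.
#' @return List with `D`, `p_naive`, `p_lilliefors`.
#' @export
ks_normality <- function(x) {
  if (length(x) < 5L) stop_ctx("need n >= 5")
  if (stats::sd(x) == 0) stop_ctx("constant sample")
  naive <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  lil <- nortest::lillie.test(x)
  list(D = unname(naive$statistic), p_naive = unname(naive$p.value),
       p_lilliefors = unname(lil$p.value))
}

#' Intra-class correlation (two-way consistency, single measures)
#'
#' Measurement repeatability between two replicate measurement sessions or
#' observers: `ICC(C,1) = (MS_subjects - MS_error) /
#' (MS_subjects + (k - 1) MS_error)` from the two-way
#' (subjects x measures) mean squares.
#'
#' @param replicates Numeric `n x k` matrix (k replicate measurements per
#'   subject, usually k = 2).
#' @return Scalar in `[-1, 1]`.
#' @export
icc_consistency <- function(replicates) {
  m <- as.matrix(replicates)
  n <- nrow(m); k <- ncol(m)
  if (n < 3L || k < 2L) stop_ctx("need >= 3 subjects and >= 2 replicates")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  if (ms_rows <= 0) stop_ctx("zero between-subject variance")
  (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
}

#' Paired t test
#'
#' @param x1,x2 Paired numeric samples of equal length `>= 2`.
#' @return List with `t`, `df`, `p`, and `degenerate = TRUE` when the
#'   differences have zero variance.
#' @export
paired_t <- function(x1, x2) {
  if (length(x1) != length(x2) || length(x1) < 2L)
    stop_ctx("paired samples must have equal length >= 2")
  d <- x1 - x2
  if (stats::sd(d) == 0)
    return(list(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                degenerate = TRUE))
  fit <- stats::t.test(d)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value), degenerate = FALSE)
}

#' Bonferroni-corrected significance threshold
#' @param alpha Family-wise error rate.
#' @param m Number of comparisons.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(is_count(m), m >= 1, alpha > 0, alpha <= 1)
  alpha / m
}

#' REML variance components for crossed random effects
#'
#' Fits `y = mu + a_species + b_year + e` with species and moult year as
#' crossed random effects by restricted maximum likelihood (`lme4::lmer`),
#' and reports the three variance components and their percentages of the
#' total. An optional species:year interaction component can be added.
#'
#' @param y Numeric response (one isotope variable).
#' @param species,year Random-effect grouping labels (>= 2 levels each).
#' @param interaction Add a species:year component (default `FALSE`).
#' @return A list of class `variance_components`: `components` (named
#'   vector, includes `error`), `percent` (summing to 100), `converged`.
#' @export
reml_varcomp <- function(y, species, year, interaction = FALSE) {
  dat <- data.frame(y = y, species = factor(species), year = factor(year))
  if (nlevels(dat$species) < 2L || nlevels(dat$year) < 2L)
    stop_ctx("need >= 2 levels for each random factor")
  form <- if (interaction)
    y ~ 1 + (1 | species) + (1 | year) + (1 | species:year)
  else y ~ 1 + (1 | species) + (1 | year)
  converged <- TRUE
  fit <- withCallingHandlers(
    lme4::lmer(form, data = dat, REML = TRUE),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- stats::setNames(vc$vcov, sub("Residual", "error", vc$grp))
  ord <- c("species", "year", if (interaction) "species:year", "error")
  comp <- comp[ord]
  structure(list(components = comp, percent = 100 * comp / sum(comp),
                 converged = converged),
            class = "variance_components")
}
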