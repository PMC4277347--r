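#' Fit an equal-prior linear discriminant function
#'
#' Two-group LDA with pooled within-group covariance (divisor `n - 2`) and
#' Fisher classification function coefficients: for group g,
#' `c_g = S^-1 mu_g` and constant `-mu_g' S^-1 mu_g / 2 + log(prior_g)`.
#' A bird is classified to the group with the larger score, which under
#' equal priors is the group with the smaller Mahalanobis distance.
#'
#' @param x Numeric `n x p` feature matrix.
#' @param grouping Factor or character vector with exactly two levels.
#' @param priors Prior probabilities (default equal), summing to 1.
#' @return A list of class `dfa_model`: `levels`, `group_means` (`2 x p`),
#'   `pooled_cov`, `priors`, `coefficients` (`p x 2` Fisher coefficients),
#'   `constants`, `feature_names`, `counts`.
#' @export
fit_lda <- function(x, grouping, priors = c(0.5, 0.5)) {
  x <- as.matrix(x)
  g <- factor(grouping)
  if (nlevels(g) != 2L) stop_ctx("fit_lda handles exactly two groups")
  if (length(priors) != 2L || abs(sum(priors) - 1) > 1e-8)
    stop_ctx("priors must be two values summing to 1")
  p <- ncol(x)
  counts <- table(g)
  if (any(counts <= p))
    stop_ctx("each group needs more observations than features")
  means <- rbind(colMeans(x[g == levels(g)[1], , drop = FALSE]),
                 colMeans(x[g == levels(g)[2], , drop = FALSE]))
  rownames(means) <- levels(g)
  n <- nrow(x)
  s <- matrix(0, p, p)
  for (lv in levels(g)) {
    xi <- x[g == lv, , drop = FALSE]
    xc <- sweep(xi, 2, colMeans(xi))
    s <- s + crossprod(xc)
  }
  s <- s / (n - 2)
  si <- tryCatch(solve(s), error = function(e)
    stop_ctx("pooled covariance is singular"))
  coef <- si %*% t(means)
  const <- -0.5 * diag(means %*% si %*% t(means)) + log(priors)
  structure(list(levels = levels(g), group_means = means, pooled_cov = s,
                 priors = priors, coefficients = coef, constants = const,
                 feature_names = colnames(x) %||% paste0("V", seq_len(p)),
                 counts = as.integer(counts)),
            class = "dfa_model")
}

#' Classify observations with a fitted discriminant function
#'
#' @param object A `dfa_model`.
#' @param newdata Numeric matrix with the model's features.
#' @param ... Unused.
#' @return Character vector of predicted group labels.
#' @export
predict.dfa_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  scores <- newdata %*% object$coefficients
  scores <- sweep(scores, 2, object$constants, "+")
  object$levels[max.col(scores, ties.method = "first")]
}

#' Jackknife (leave-one-out) cross-validated accuracy
#'
#' Refits the discriminant function without bird i and classifies bird i,
#' for every i; reports the correctly classified fraction per group and
#' overall.
#'
#' @inheritParams fit_lda
#' @return List with `overall`, `by_group` (named), and `predicted`.
#' @export
jackknife_cv <- function(x, grouping, priors = c(0.5, 0.5)) {
  x <- as.matrix(x)
  g <- factor(grouping)
  n <- nrow(x)
  if (any(table(g) < 3L)) stop_ctx("jackknife needs >= 3 birds per group")
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- fit_lda(x[-i, , drop = FALSE], g[-i], priors)
    pred[i] <- predict(fit, x[i, , drop = FALSE])
  }
  correct <- pred == as.character(g)
  list(overall = mean(correct),
       by_group = vapply(levels(g), function(lv) mean(correct[g == lv]),
                         numeric(1)),
       predicted = pred)
}

#' Stratified train/test split
#'
#' Randomly partitions each group into a training set of the requested size
#' and a test set of the remainder. Defaults to 80% training per group;
#' explicit counts (e.g. the 40 YS / 50 BS training split of the study) can
#' be supplied.
#'
#' @param grouping Factor or character vector of group labels.
#' @param counts Named integer vector of per-group training sizes, or
#'   `NULL` for `round(0.8 * n_g)`.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(grouping, counts = NULL, seed = 1L) {
  g <- factor(grouping)
  sizes <- table(g)
  if (is.null(counts)) {
    counts <- round(0.8 * sizes)
    names(counts) <- levels(g)
  }
  if (!all(levels(g) %in% names(counts)))
    stop_ctx("counts must name every group")
  if (any(counts[levels(g)] > sizes))
    stop_ctx("training counts exceed group sizes")
  train <- integer(0)
  with_seed(seed, {
    for (lv in levels(g)) {
      idx <- which(g == lv)
      train <- c(train, sort(sample(idx, counts[[lv]])))
    }
  })
  test <- setdiff(seq_along(g), train)
  if (!length(test)) warning("empty test set: training counts equal group sizes")
  list(train = sort(train), test = test)
}

#' Three-criteria assignment rule for the extension cohort
#'
#' Birds of the extension cohort (no genetic data) are assigned a species
#' only when plumage colouration and the biometric and isotopic
#' discriminant functions all agree; doubtful plumage, or any disagreement,
#' yields `"unknown"`.
#'
#' @param plumage_call,biometric_dfa_call,isotope_dfa_call Character
#'   vectors of calls (`"YS"`, `"BS"`; plumage may be `"doubtful"`).
#' @return Character vector in `{"YS","BS","unknown"}`.
#' @export
assign_dataset2 <- function(plumage_call, biometric_dfa_call, isotope_dfa_call) {
  n <- length(plumage_call)
  stopifnot(length(biometric_dfa_call) == n, length(isotope_dfa_call) == n)
  out <- rep("unknown", n)
  ok <- plumage_call %in% species_levels() &
    plumage_call == biometric_dfa_call & plumage_call == isotope_dfa_call
  out[ok] <- plumage_call[ok]
  out
}
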