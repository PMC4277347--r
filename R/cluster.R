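#' Partitioning around medoids (deterministic PAM)
#'
#' k-medoids clustering of a dissimilarity matrix. Tiny instances
#' (`choose(n, k) <= 1500`) are solved exactly by enumerating all medoid
#' subsets; larger ones use the classic local search: a greedy BUILD phase
#' (each new medoid maximizes the drop in total dissimilarity to the nearest
#' medoid) followed by a SWAP phase that repeatedly applies the best
#' cost-improving medoid/non-medoid exchange until none improves. Both
#' routes are fully deterministic; all ties break toward the lowest index
#' (lexicographically smallest subset for the exact route).
#'
#' @param d Dissimilarity input: a [as_dist_matrix()] matrix, `dist`, or a
#'   numeric feature matrix (converted to Euclidean distances).
#' @param k Number of clusters, `2 <= k < n`.
#' @return A list of class `cluster_result`: `k`, `labels` (1..k, named by
#'   point ids; clusters numbered by ascending medoid index), `medoids`
#'   (indices), `medoid_ids`, `cost`, `avg_silhouette`,
#'   `per_point_silhouette`.
#' @export
pam_cluster <- function(d, k) {
  d <- to_dist_matrix(d)
  n <- nrow(d)
  if (!is_count(k) || k < 2L || k >= n) stop_ctx("k must satisfy 2 <= k < n")
  dm <- unclass(d)

  total_cost <- function(meds)
    sum(do.call(pmin, lapply(meds, function(m) dm[, m])))

  if (choose(n, k) <= 1500) {
    # exact: enumerate every medoid subset; combn order makes the first
    # minimum the lexicographically smallest subset
    combs <- utils::combn(n, k)
    costs <- apply(combs, 2, total_cost)
    medoids <- combs[, which.min(costs)]
    cost <- min(costs)
    cost_trace <- cost
  } else {
    # BUILD
    medoids <- integer(0)
    nearest <- rep(Inf, n)
    for (step in seq_len(k)) {
      if (step == 1L) {
        tot <- colSums(dm)
        cand <- which.min(tot)        # lowest index on ties
      } else {
        gain <- vapply(seq_len(n), function(c) {
          if (c %in% medoids) return(-Inf)
          sum(pmax(0, nearest - dm[, c]))
        }, numeric(1))
        cand <- which.max(gain)
      }
      medoids <- c(medoids, cand)
      nearest <- pmin(nearest, dm[, cand])
    }
    medoids <- sort(medoids)

    # SWAP: best-improving exchange, ties to lowest (medoid, candidate) pair
    cost <- total_cost(medoids)
    cost_trace <- cost
    repeat {
      best <- list(cost = cost)
      for (m in medoids) for (h in seq_len(n)) {
        if (h %in% medoids) next
        trial <- sort(c(setdiff(medoids, m), h))
        tc <- total_cost(trial)
        if (tc < best$cost - 1e-12) best <- list(cost = tc, meds = trial)
      }
      if (is.null(best$meds)) break
      medoids <- best$meds
      cost <- best$cost
      cost_trace <- c(cost_trace, cost)
    }
  }

  assign_idx <- max.col(-dm[, medoids, drop = FALSE], ties.method = "first")
  labels <- stats::setNames(as.integer(assign_idx), rownames(dm))
  sil <- silhouette_widths(d, labels)
  structure(list(k = k, labels = labels, medoids = medoids,
                 medoid_ids = rownames(dm)[medoids], cost = cost,
                 avg_silhouette = sil$average,
                 per_point_silhouette = sil$widths,
                 cost_trace = cost_trace),
            class = "cluster_result")
}

to_dist_matrix <- function(d) {
  if (inherits(d, "dist_matrix")) return(d)
  if (inherits(d, "dist")) return(as_dist_matrix(as.matrix(d)))
  d <- as.matrix(d)
  if (nrow(d) == ncol(d) && !is.null(rownames(d)) &&
      identical(rownames(d), colnames(d)) && all(diag(d) == 0) &&
      isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    return(as_dist_matrix(d))
  if (is.null(rownames(d))) rownames(d) <- as.character(seq_len(nrow(d)))
  m <- as.matrix(stats::dist(d))
  dimnames(m) <- list(rownames(d), rownames(d))
  as_dist_matrix(m)
}

#' Silhouette widths
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)` the mean
#' dissimilarity of `i` to its own cluster (excluding itself) and `b(i)` the
#' smallest mean dissimilarity to any other cluster. Members of singleton
#' clusters get `s = 0`.
#'
#' @param d Dissimilarity input (as in [pam_cluster()]).
#' @param labels Integer cluster labels.
#' @return List with `widths` (per point) and `average`.
#' @export
silhouette_widths <- function(d, labels) {
  d <- to_dist_matrix(d)
  dm <- unclass(d)
  n <- nrow(dm)
  stopifnot(length(labels) == n)
  cl <- sort(unique(labels))
  if (length(cl) < 2L) stop_ctx("silhouette needs >= 2 clusters")
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(dm[i, setdiff(own, i)])
    b <- min(vapply(setdiff(cl, labels[i]),
                    function(g) mean(dm[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  list(widths = stats::setNames(s, rownames(dm)), average = mean(s))
}

#' Estimate the number of clusters by average silhouette width
#'
#' Runs [pam_cluster()] for each `k` in `k_range` and returns the `k`
#' maximizing the average silhouette width (ties toward the smallest `k`).
#'
#' @param d Dissimilarity input.
#' @param k_range Integer vector of candidate cluster numbers.
#' @return List with `k` (the estimate) and `avg_silhouette` (named vector
#'   over the candidates).
#' @export
estimate_k <- function(d, k_range = 2:6) {
  d <- to_dist_matrix(d)
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range)) stop_ctx("empty k_range")
  if (min(k_range) < 2L || max(k_range) >= nrow(d))
    stop_ctx("k_range must lie within [2, n-1]")
  avg <- vapply(k_range, function(k) pam_cluster(d, k)$avg_silhouette, numeric(1))
  names(avg) <- k_range
  list(k = k_range[which.max(avg)], avg_silhouette = avg)
}

#' Bootstrap Jaccard cluster stability
#'
#' For each of `runs` bootstrap resamples (n draws with replacement; for a
#' dissimilarity input, the induced submatrix), the resample is reclustered
#' with PAM at the same `k`; each original cluster is then matched to the
#' bootstrap cluster maximizing the Jaccard coefficient
#' `|C n D| / |C u D|`, computed on the distinct resampled points. The mean
#' Jaccard over runs is reported per cluster, with clusters flagged stable
#' when it reaches `threshold` (conventionally 0.75). Resamples with fewer
#' than `k` distinct points are redrawn.
#'
#' @param d Dissimilarity or feature input.
#' @param k Number of clusters.
#' @param runs Number of bootstrap resamples (default 100; the study-scale
#'   setting is 10000).
#' @param seed Integer seed.
#' @param threshold Stability threshold (default 0.75).
#' @return A list: `jaccard` (k-vector of means), `stable` (logical),
#'   `result` (the original [pam_cluster()] fit), `runs`, `threshold`.
#' @export
bootstrap_stability <- function(d, k, runs = 100L, seed = 1L, threshold = 0.75) {
  d <- to_dist_matrix(d)
  stopifnot(is_count(runs), runs >= 1)
  n <- nrow(d)
  base <- pam_cluster(d, k)
  orig <- split(seq_len(n), base$labels)
  jac <- matrix(0, runs, k)
  with_seed(seed, {
    for (r in seq_len(runs)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(idx)) >= k + 1L) break
      }
      sub <- unclass(d)[idx, idx]
      rownames(sub) <- colnames(sub) <- as.character(seq_len(n))
      fit <- pam_cluster(as_dist_matrix(sub), k)
      uniq <- unique(idx)
      boot_cl <- lapply(split(idx, fit$labels), unique)
      for (g in seq_len(k)) {
        cg <- intersect(orig[[g]], uniq)
        jac[r, g] <- if (!length(cg)) 0 else
          max(vapply(boot_cl, function(dset)
            length(intersect(cg, dset)) / length(union(cg, dset)), numeric(1)))
      }
    }
  })
  m <- colMeans(jac)
  list(jaccard = m, stable = m >= threshold, result = base,
       runs = runs, threshold = threshold)
}

#' Classical (metric) multidimensional scaling
#'
#' Torgerson scaling of a dissimilarity matrix: double-centre the squared
#' dissimilarities, eigendecompose, and scale the eigenvectors by the square
#' roots of the positive eigenvalues (descending). A thin wrapper around
#' `stats::cmdscale` returning all eigenvalues.
#'
#' @param d Dissimilarity input.
#' @param dims Number of coordinates (default 2), `dims <= n - 1`.
#' @return List with `coordinates` (`n x dims`, row-named) and
#'   `eigenvalues` (all `n`).
#' @export
classical_mds <- function(d, dims = 2L) {
  d <- to_dist_matrix(d)
  n <- nrow(d)
  if (!is_count(dims) || dims < 1L || dims > n - 1L)
    stop_ctx("dims must lie in [1, n-1]")
  fit <- stats::cmdscale(stats::as.dist(unclass(d)), k = dims, eig = TRUE)
  if (all(fit$eig <= 0)) stop_ctx("no positive eigenvalues: degenerate input")
  co <- fit$points
  if (ncol(co) < dims) {  # pad dimensions lost to non-positive eigenvalues
    co <- cbind(co, matrix(0, n, dims - ncol(co)))
  }
  rownames(co) <- rownames(unclass(d))
  list(coordinates = co, eigenvalues = fit$eig)
}
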