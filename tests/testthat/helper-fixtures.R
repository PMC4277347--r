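# Shared fixture builders. Everything is generated in code at test time.

# n points per group around two far-apart centres; rownames required by the
# distance machinery.
two_blob_features <- function(n_per = 20, sep = 10, sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(stats::rnorm(2 * n_per, 0, sd), n_per),
               matrix(stats::rnorm(2 * n_per, sep, sd), n_per))
  })
  rownames(x) <- sprintf("p%02d", seq_len(nrow(x)))
  x
}

# Euclidean dist_matrix from a feature matrix.
feature_dist <- function(x) {
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(rownames(x), rownames(x))
  as_dist_matrix(d)
}

# Random landmark configurations: template + noise, arbitrary pose.
random_landmark_set <- function(n = 20, noise = 0.1, seed = 1) {
  simulate_landmarks("YS", n, sim_params(landmark_noise_sd = noise),
                     seed = seed)
}

# A small bird table fixture written to a temp file.
write_bird_fixture <- function(path, sep = ",") {
  df <- data.frame(
    id = c("B001", "B002", "B003"),
    source = c("bycatch", "bycatch", "reference_ys"),
    sex = c("male", "female", "male"),
    plumage_call = c("YS", "doubtful", "YS"),
    bill_depth_base = c(11.2, 12.1, 11.4),
    wing_length = c(241, 252, NA),
    d15N_P1 = c(11.1, 14.2, 11.5),
    true_species = c("YS", "BS", "YS"),
    stringsAsFactors = FALSE)
  write_bird_table(df, path, sep = sep)
  df
}

# Brute-force k-medoids cost by full enumeration.
brute_force_pam_cost <- function(dm, k) {
  combs <- utils::combn(nrow(dm), k)
  min(apply(combs, 2, function(m)
    sum(apply(dm[, m, drop = FALSE], 1, min))))
}

# Bisection on the PSD predicate: smallest additive constant making the
# double-centred Gram matrix positive semi-definite.
bisect_cailliez <- function(d, iters = 60) {
  n <- nrow(d)
  j <- diag(n) - 1 / n
  psd <- function(cc) {
    dc <- d + cc; diag(dc) <- 0
    ev <- eigen(-0.5 * j %*% (dc^2) %*% j, symmetric = TRUE,
                only.values = TRUE)$values
    ev[n] >= -1e-10 * max(ev[1], 1)
  }
  lo <- 0; hi <- max(d) * 3 + 1
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (psd(mid)) hi <- mid else lo <- mid
  }
  hi
}
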