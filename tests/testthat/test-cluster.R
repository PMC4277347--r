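test_that("pam separates obvious pairs and is optimal on small instances", {
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  fit <- pam_cluster(x, 2)
  expect_equal(unname(fit$labels), c(1L, 1L, 2L, 2L))
  expect_error(pam_cluster(x, 4), "k must")

  withr::with_seed(42, {
    for (r in 1:30) {
      n <- sample(8:12, 1); k <- sample(2:3, 1)
      pts <- matrix(rnorm(n * 2), n, dimnames = list(paste0("p", 1:n), NULL))
      d <- feature_dist(pts)
      fit <- pam_cluster(d, k)
      expect_equal(fit$cost, brute_force_pam_cost(unclass(d), k),
                   tolerance = 1e-10)
    }
  })
})

test_that("duplicating every point preserves medoid values and doubles cost", {
  x <- two_blob_features(6, seed = 4)
  fit1 <- pam_cluster(x, 2)
  x2 <- rbind(x, x)
  rownames(x2) <- sprintf("q%02d", seq_len(nrow(x2)))
  fit2 <- pam_cluster(x2, 2)
  med1 <- x[fit1$medoids, , drop = FALSE]
  med2 <- x2[fit2$medoids, , drop = FALSE]
  expect_equal(sort(unname(med1[, 1])), sort(unname(med2[, 1])),
               tolerance = 1e-12)
  expect_equal(fit2$cost, 2 * fit1$cost, tolerance = 1e-10)
})

test_that("pam is invariant to row permutation up to label renaming", {
  x <- two_blob_features(8, seed = 5)
  fit <- pam_cluster(x, 2)
  perm <- rev(seq_len(nrow(x)))
  fitp <- pam_cluster(x[perm, ], 2)
  expect_setequal(names(fit$labels)[fit$labels == fit$labels[["p01"]]],
                  names(fitp$labels)[fitp$labels == fitp$labels[["p01"]]])
  expect_equal(fit$cost, fitp$cost, tolerance = 1e-12)
})

test_that("silhouette matches hand arithmetic and the reference implementation", {
  d <- matrix(c(0, 1, 5, 6,
                1, 0, 5.5, 6.5,
                5, 5.5, 0, 1.2,
                6, 6.5, 1.2, 0), 4, 4, dimnames = list(1:4, 1:4))
  lab <- c(1L, 1L, 2L, 2L)
  sil <- silhouette_widths(as_dist_matrix(d), lab)
  # hand computation: a(1) = 1, b(1) = mean(5,6) = 5.5
  expect_equal(unname(sil$widths[1]), (5.5 - 1) / 5.5, tolerance = 1e-12)
  expect_equal(unname(sil$widths[3]), ((5 + 5.5) / 2 - 1.2) / ((5 + 5.5) / 2),
               tolerance = 1e-12)
  ref <- cluster::silhouette(lab, stats::as.dist(d))
  expect_equal(unname(sil$widths), unname(ref[, 3]), tolerance = 1e-12)
})

test_that("silhouette is ~0 for an equidistant point and high for tight clusters", {
  # symmetric instance: point c is equidistant to both cluster means
  d <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  d["a", "b"] <- d["b", "a"] <- 1
  d["d", "e"] <- d["e", "d"] <- 1
  for (p in c("a", "b")) { d[p, "c"] <- d["c", p] <- 3 }
  for (p in c("d", "e")) { d[p, "c"] <- d["c", p] <- 3 }
  for (p in c("a", "b")) for (q in c("d", "e")) { d[p, q] <- d[q, p] <- 6 }
  lab <- c(1L, 1L, 1L, 2L, 2L)
  sil <- silhouette_widths(as_dist_matrix(d), lab)
  expect_lt(abs(sil$widths[["c"]]), 1e-12)  # a = 3 = b -> s = 0

  x <- two_blob_features(10, sep = 10, sd = 0.1, seed = 6)
  fit <- pam_cluster(x, 2)
  expect_gt(fit$avg_silhouette, 0.9)
})

test_that("silhouette-based k estimation finds the simulated group number", {
  expect_equal(estimate_k(two_blob_features(20, seed = 7), 2:5)$k, 2L)
  withr::with_seed(8, {
    x3 <- rbind(matrix(rnorm(30, 0, 0.5), 15),
                matrix(rnorm(30, 10, 0.5), 15),
                matrix(rnorm(30, 20, 0.5), 15))
  })
  rownames(x3) <- paste0("p", 1:45)
  expect_equal(estimate_k(x3, 2:5)$k, 3L)
  expect_equal(estimate_k(two_blob_features(5, seed = 1), 2)$k, 2L)
  expect_error(estimate_k(two_blob_features(5, seed = 1), integer()), "k_range")
})

test_that("bootstrap stability is high for separated and low for structureless data", {
  bs <- bootstrap_stability(two_blob_features(20, seed = 9), 2,
                            runs = 100, seed = 10)
  expect_true(all(bs$jaccard >= 0.95))
  expect_true(all(bs$stable))

  withr::with_seed(11, xu <- matrix(runif(300), 30,
                                    dimnames = list(paste0("p", 1:30), NULL)))
  bu <- bootstrap_stability(xu, 2, runs = 100, seed = 10)
  expect_lt(min(bu$jaccard), 0.75)
  expect_false(all(bu$stable))
  # reproducible under a fixed seed; means bounded
  bu2 <- bootstrap_stability(xu, 2, runs = 100, seed = 10)
  expect_identical(bu$jaccard, bu2$jaccard)
  expect_true(all(bu$jaccard >= 0 & bu$jaccard <= 1))
})

test_that("a resample reproducing the original clusters scores Jaccard 1", {
  # 4 points, 2 tight pairs: any resample with >= 2 distinct points per
  # pair reclusters identically, so every run scores 1 for both clusters
  x <- matrix(c(0, 0.01, 10, 10.01), ncol = 1,
              dimnames = list(paste0("p", 1:4), NULL))
  bs <- bootstrap_stability(x, 2, runs = 20, seed = 3)
  expect_equal(bs$jaccard, c(1, 1))
})

test_that("classical MDS reproduces known geometries", {
  # collinear points at 0, 3, 7
  d <- feature_dist(matrix(c(0, 3, 7), ncol = 1,
                           dimnames = list(c("a", "b", "c"), NULL)))
  mds <- classical_mds(d, dims = 1)
  got <- sort(unname(stats::dist(mds$coordinates)))
  expect_equal(got, c(3, 4, 7), tolerance = 1e-10)

  # 3-4-5 right triangle round-trips through a 2-D embedding
  tri <- matrix(c(0, 0, 3, 0, 3, 4), 3, 2, byrow = TRUE,
                dimnames = list(1:3, NULL))
  dt <- feature_dist(tri)
  co <- classical_mds(dt, dims = 2)$coordinates
  expect_equal(as.matrix(stats::dist(co)), unclass(dt), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(classical_mds(dt, dims = 3), "dims")
})
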