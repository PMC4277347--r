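test_that("centroid size matches the direct formula and scales linearly", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)
  expect_equal(centroid_size(sq * 3), 3 * sqrt(2), tolerance = 1e-12)
  # brute-force oracle on a random 13-point configuration
  withr::with_seed(4, pts <- matrix(rnorm(26), 13, 2))
  ctr <- colMeans(pts)
  brute <- sqrt(sum(vapply(seq_len(13), function(i)
    sum((pts[i, ] - ctr)^2), numeric(1))))
  expect_equal(centroid_size(pts), brute, tolerance = 1e-12)
  # rotation/translation invariance
  th <- 0.71; rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(centroid_size(sweep(pts %*% rot, 2, c(5, -2), "+")),
               centroid_size(pts), tolerance = 1e-12)
  expect_warning(centroid_size(matrix(1, 4, 2)), "degenerate")
})

test_that("GPA recovers exact-fit similarity copies and ignores input order", {
  tmpl <- sim_params()$template$points
  withr::with_seed(8, {
    copies <- lapply(1:20, function(i) {
      th <- runif(1, 0, 2 * pi)
      rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      landmark_config(sweep(tmpl %*% rot * runif(1, 0.5, 2), 2,
                            runif(2, -5, 5), "+"), id = i)
    })
  })
  gpa <- gpa_align(copies, slide = FALSE)
  flat <- matrix(gpa$aligned, 20, 26)
  expect_lt(max(stats::dist(flat)), 1e-10)
  # unit centroid size invariant
  cs <- apply(gpa$aligned, 1, function(m) centroid_size(m))
  expect_equal(cs, rep(1, 20), tolerance = 1e-12)

  set <- random_landmark_set(15, seed = 2)
  m1 <- gpa_align(set, slide = FALSE)$mean_shape
  m2 <- gpa_align(rev(set), slide = FALSE)$mean_shape
  # align the two means before comparing (rotation is conventionally free)
  m2 <- m2 %*% shearid:::procrustes_rotation(m2, m1)
  expect_lt(sqrt(sum((m1 - m2)^2)), 1e-6)
  # with sliding the tangential position of slid points is a neutral
  # direction, so order invariance holds only up to that drift
  s1 <- gpa_align(set)$mean_shape
  s2 <- gpa_align(rev(set))$mean_shape
  s2 <- s2 %*% shearid:::procrustes_rotation(s2, s1)
  expect_lt(sqrt(sum((s1 - s2)^2)), 0.02)
})

test_that("two-configuration rotation equals the closed-form Procrustes solution", {
  a <- rbind(c(0, 0), c(2, 0), c(1, 2))
  th <- 0.9
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  b <- a %*% rot
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  # closed form via SVD of the cross-covariance
  sv <- svd(crossprod(bc, ac))
  closed <- sv$u %*% t(sv$v)
  got <- shearid:::procrustes_rotation(bc, ac)
  expect_equal(got, closed, tolerance = 1e-12)
  expect_equal(bc %*% got, ac, tolerance = 1e-12)
  expect_equal(det(got), 1, tolerance = 1e-12)
})

test_that("GPA is invariant to arbitrary pre-transformation of the inputs", {
  set <- random_landmark_set(12, seed = 3)
  withr::with_seed(9, {
    mangled <- lapply(set, function(cf) {
      th <- runif(1, 0, 2 * pi)
      rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      landmark_config(sweep(cf$points %*% rot * runif(1, 0.2, 5), 2,
                            runif(2, -100, 100), "+"), id = cf$id)
    })
  })
  g1 <- gpa_align(set); g2 <- gpa_align(mangled)
  m2 <- g2$mean_shape %*% shearid:::procrustes_rotation(g2$mean_shape, g1$mean_shape)
  expect_lt(sqrt(sum((g1$mean_shape - m2)^2)), 1e-6)
})

test_that("sliding projects onto the tangent and never increases distance to the mean", {
  gpa <- gpa_align(random_landmark_set(10, seed = 5), slide = FALSE)
  x <- gpa$aligned; m <- gpa$mean_shape
  roles <- gpa$roles; co <- gpa$curve_order
  slid <- slide_semilandmarks(x, m, roles, co)
  semis <- which(roles == "semilandmark")
  for (i in seq_len(dim(x)[1])) {
    before <- sum((x[i, semis, ] - m[semis, ])^2)
    after <- sum((slid[i, semis, ] - m[semis, ])^2)
    expect_lte(after, before + 1e-15)
  }
  # specimen identical to the mean does not move
  x1 <- x; x1[1, , ] <- m
  slid1 <- slide_semilandmarks(x1, m, roles, co)
  expect_equal(slid1[1, , ], m, tolerance = 1e-14)
  # a semilandmark displaced purely along its own tangent lands on the mean
  x2 <- x; x2[2, , ] <- m
  j <- semis[2]; pos <- match(j, co)
  u <- m[co[pos + 1], ] - m[co[pos - 1], ]; u <- u / sqrt(sum(u^2))
  x2[2, j, ] <- m[j, ] + 0.03 * u
  slid2 <- slide_semilandmarks(x2, m, roles, co)
  expect_equal(slid2[2, j, ], m[j, ], tolerance = 1e-12)
})

test_that("slide positions match a dense 1-D grid search along the tangent", {
  gpa <- gpa_align(random_landmark_set(6, seed = 12), slide = FALSE)
  x <- gpa$aligned; m <- gpa$mean_shape
  slid <- slide_semilandmarks(x, m, gpa$roles, gpa$curve_order)
  semis <- which(gpa$roles == "semilandmark")
  co <- gpa$curve_order
  for (i in seq_len(dim(x)[1])) for (s in seq_along(semis)) {
    j <- semis[s]; pos <- match(j, co)
    chord <- x[i, co[pos + 1], ] - x[i, co[pos - 1], ]
    u <- chord / sqrt(sum(chord^2))
    ts <- seq(-0.5, 0.5, by = 1e-5)
    cand_x <- x[i, j, 1] + ts * u[1]
    cand_y <- x[i, j, 2] + ts * u[2]
    best <- which.min((cand_x - m[j, 1])^2 + (cand_y - m[j, 2])^2)
    expect_lt(max(abs(slid[i, j, ] -
                        c(cand_x[best], cand_y[best]))), 1e-5 + 1e-6)
  }
})

test_that("relative warps count 2k-4-s non-zero eigenvalues and conserve variance", {
  gpa13 <- gpa_align(random_landmark_set(50, seed = 6))
  rw <- relative_warps(gpa13)
  expect_equal(rw$n_nonzero, 19L)   # 2*13 - 4 - 3
  expect_equal(sum(rw$eigenvalues), rw$total_variance, tolerance = 1e-10)
  # scores are orthogonal
  sc <- rw$scores[, seq_len(rw$n_nonzero)]
  gram <- crossprod(sc)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8 * max(diag(gram)))

  # 10 fixed landmarks, no sliding: 2k - 4 = 16
  set10 <- lapply(random_landmark_set(50, seed = 7), function(cf)
    landmark_config(cf$points[1:10, ], id = cf$id))
  rw10 <- relative_warps(gpa_align(set10))
  expect_equal(rw10$n_nonzero, 16L)

  # 5 fixed landmarks: 2k - 4 = 6
  set5 <- lapply(random_landmark_set(40, seed = 8), function(cf)
    landmark_config(cf$points[c(1, 2, 3, 9, 10), ], id = cf$id))
  expect_equal(relative_warps(gpa_align(set5))$n_nonzero, 6L)
})
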