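#' Centroid size of a landmark configuration
#'
#' Centroid size (CS) is the square root of the summed squared distances of
#' each landmark from the centroid of the configuration. It is invariant to
#' rotation and translation and scales linearly under isotropic scaling.
#'
#' @param config A [landmark_config()] or a `k x 2` coordinate matrix.
#' @return Positive scalar (mm); 0 with a warning if all points coincide.
#' @export
centroid_size <- function(config) {
  pts <- if (inherits(config, "landmark_config")) config$points else as.matrix(config)
  if (nrow(pts) < 2L) stop_ctx("centroid size needs >= 2 points")
  ctd <- sweep(pts, 2, colMeans(pts))
  cs <- sqrt(sum(ctd^2))
  if (cs == 0) warning("degenerate configuration: all points coincident")
  cs
}

# Optimal proper (det +1) rotation of centred X onto centred Y.
procrustes_rotation <- function(x, y) {
  m <- crossprod(x, y)
  sv <- svd(m)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$u %*% diag(c(1, d)) %*% t(sv$v)
}

center_scale <- function(pts) {
  ctd <- sweep(pts, 2, colMeans(pts))
  cs <- sqrt(sum(ctd^2))
  if (cs == 0) stop_ctx("degenerate configuration (centroid size 0)")
  ctd / cs
}

#' Generalized Procrustes Analysis with optional sliding semilandmarks
#'
#' Superimposes a set of 2-D landmark configurations: each is centred,
#' scaled to unit centroid size, and rotated (proper rotations only; the
#' photographs are all of the same bill side, so reflections are
#' disallowed) onto an iteratively updated mean shape. When `slide = TRUE`,
#' each outer iteration interleaves semilandmark sliding along the outline
#' tangent using the minimum Procrustes distance criterion (see
#' [slide_semilandmarks()]). Iteration stops when the mean shape changes by
#' less than `tol` in root summed squares.
#'
#' @param configs List of [landmark_config()] objects with identical point
#'   counts and roles.
#' @param slide Slide the semilandmarks (default `TRUE` when the
#'   configurations declare any).
#' @param tol Convergence tolerance on the mean shape (default 1e-8).
#' @param slide_tol With sliding, iteration also stops once the total
#'   Procrustes sum of squares improves by less than this relative amount
#'   per iteration (default 1e-4). The tangential position of slid points
#'   is a neutral direction along which configurations creep with
#'   vanishing effect on fit, so the objective -- not the mean shape -- is
#'   the stable convergence target.
#' @param max_iter Maximum outer iterations (default 100).
#' @return An object of class `aligned_shapes`: list with `aligned`
#'   (`n x k x 2` array), `csize` (original centroid sizes, mm),
#'   `mean_shape` (`k x 2`, unit CS), `ids`, `roles`, `curve_order`,
#'   `slide`, `iterations`.
#' @export
gpa_align <- function(configs, slide = NULL, tol = 1e-8, slide_tol = 1e-4,
                      max_iter = 100L) {
  if (length(configs) < 2L) stop_ctx("GPA needs >= 2 configurations")
  k <- nrow(configs[[1]]$points)
  roles <- configs[[1]]$roles
  curve_order <- configs[[1]]$curve_order
  for (cf in configs)
    if (nrow(cf$points) != k || !identical(cf$roles, roles))
      stop_ctx("configurations must share point count and roles")
  if (is.null(slide)) slide <- any(roles == "semilandmark")
  if (slide && !any(roles == "semilandmark"))
    stop_ctx("slide = TRUE but no semilandmarks declared")

  n <- length(configs)
  csize <- vapply(configs, function(cf) centroid_size(cf$points), numeric(1))
  x <- array(0, c(n, k, 2))
  for (i in seq_len(n)) x[i, , ] <- center_scale(configs[[i]]$points)

  # Convergence is judged on the mean shape for plain GPA and on the total
  # Procrustes sum of squares when sliding: the tangential position of slid
  # points is a neutral direction along which the mean can drift without
  # changing fit, so the objective -- not the mean -- is the stable target.
  mean_shape <- x[1, , ]
  it <- 0L; change <- Inf; ss_prev <- Inf; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    for (i in seq_len(n))
      x[i, , ] <- x[i, , ] %*% procrustes_rotation(x[i, , ], mean_shape)
    if (slide) {
      x <- slide_semilandmarks(x, mean_shape, roles, curve_order)
      for (i in seq_len(n)) {
        x[i, , ] <- center_scale(x[i, , ])
        x[i, , ] <- x[i, , ] %*% procrustes_rotation(x[i, , ], mean_shape)
      }
    }
    new_mean <- apply(x, c(2, 3), mean)
    new_mean <- center_scale(new_mean)
    new_mean <- new_mean %*% procrustes_rotation(new_mean, mean_shape)
    change <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    ss <- sum(sweep(x, c(2, 3), mean_shape)^2)
    if (change < tol ||
        (slide && abs(ss_prev - ss) < slide_tol * max(ss, 1e-12))) {
      converged <- TRUE
      break
    }
    ss_prev <- ss
  }
  if (!converged)
    stop_ctx("GPA did not converge: last mean change ", format(change))
  for (i in seq_len(n))
    x[i, , ] <- x[i, , ] %*% procrustes_rotation(x[i, , ], mean_shape)
  structure(list(aligned = x, csize = csize, mean_shape = mean_shape,
                 ids = vapply(configs, `[[`, character(1), "id"),
                 roles = roles, curve_order = curve_order, slide = slide,
                 iterations = it),
            class = "aligned_shapes")
}

#' Slide semilandmarks along their outline tangent
#'
#' For each specimen and each semilandmark `j`, the tangent is the unit
#' vector along the chord between `j`'s neighbours in `curve_order`
#' (computed from the specimen's own pre-slide coordinates), and the point
#' moves along that tangent to the position closest to the corresponding
#' mean landmark: `x_j + t u_j` with `t = u_j . (mean_j - x_j)`. Fixed
#' landmarks are untouched; each point's squared distance to the mean never
#' increases.
#'
#' @param aligned `n x k x 2` array of superimposed coordinates.
#' @param mean_shape `k x 2` mean shape.
#' @param roles Per-point `"fixed"`/`"semilandmark"` tags.
#' @param curve_order Outline index sequence the semilandmarks slide on.
#' @return Updated `n x k x 2` array.
#' @export
slide_semilandmarks <- function(aligned, mean_shape, roles, curve_order) {
  semis <- which(roles == "semilandmark")
  if (!length(semis)) return(aligned)
  pos <- match(semis, curve_order)
  if (anyNA(pos) || any(pos == 1L) || any(pos == length(curve_order)))
    stop_ctx("each semilandmark needs two neighbours in curve_order")
  prev <- curve_order[pos - 1L]
  nxt <- curve_order[pos + 1L]
  n <- dim(aligned)[1]
  for (i in seq_len(n)) {
    pts <- aligned[i, , ]
    for (s in seq_along(semis)) {
      j <- semis[s]
      chord <- pts[nxt[s], ] - pts[prev[s], ]
      len <- sqrt(sum(chord^2))
      if (len == 0) stop_ctx("coincident neighbours: tangent undefined at point ", j)
      u <- chord / len
      t <- sum(u * (mean_shape[j, ] - pts[j, ]))
      aligned[i, j, ] <- pts[j, ] + t * u
    }
  }
  aligned
}

#' Relative warps of an aligned shape set
#'
#' Principal components of the mean-centred, flattened aligned coordinates
#' with uniform and non-uniform shape variation weighted equally (bending
#' energy weight 0). Before decomposition, residuals are projected
#' orthogonally to the directions that superimposition and sliding have
#' removed from shape space -- two translations, scale (along the mean
#' shape), rotation (the mean rotated 90 degrees) and, when the set was
#' slid, the outline tangent at each semilandmark of the mean shape -- so
#' that with `k` landmarks and `s` slid semilandmarks exactly `2k - 4 - s`
#' eigenvalues are non-zero on non-degenerate data.
#'
#' @param aligned_set An `aligned_shapes` object from [gpa_align()].
#' @param zero_tol Eigenvalues below `zero_tol * lambda_1` are reported as
#'   zero (default 1e-8).
#' @return A list: `scores` (`n x m`), `eigenvalues` (descending),
#'   `n_nonzero`, `total_variance`.
#' @export
relative_warps <- function(aligned_set, zero_tol = 1e-8) {
  stopifnot(inherits(aligned_set, "aligned_shapes"))
  x <- aligned_set$aligned
  n <- dim(x)[1]; k <- dim(x)[2]
  if (n < 3L) stop_ctx("relative warps need >= 3 specimens")
  flat <- matrix(x, n, 2 * k)   # columns x1..xk, y1..yk
  flat <- sweep(flat, 2, colMeans(flat))

  m <- aligned_set$mean_shape
  constraints <- cbind(
    c(rep(1, k), rep(0, k)),            # translation x
    c(rep(0, k), rep(1, k)),            # translation y
    c(m[, 1], m[, 2]),                  # scale
    c(-m[, 2], m[, 1]))                 # rotation
  if (isTRUE(aligned_set$slide)) {
    semis <- which(aligned_set$roles == "semilandmark")
    co <- aligned_set$curve_order
    pos <- match(semis, co)
    for (s in seq_along(semis)) {
      j <- semis[s]
      chord <- m[co[pos[s] + 1L], ] - m[co[pos[s] - 1L], ]
      u <- chord / sqrt(sum(chord^2))
      v <- numeric(2 * k); v[j] <- u[1]; v[k + j] <- u[2]
      constraints <- cbind(constraints, v)
    }
  }
  q <- qr.Q(qr(constraints))
  flat <- flat - (flat %*% q) %*% t(q)

  sv <- svd(flat)
  eig <- sv$d^2 / (n - 1)
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  nz <- sum(eig > zero_tol * eig[1])
  list(scores = scores, eigenvalues = eig, n_nonzero = nz,
       total_variance = sum(flat^2) / (n - 1))
}
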