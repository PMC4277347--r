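#' Identity-based distance matrix from an aligned mtDNA fragment
#'
#' For each pair of sequences, valid sites are alignment columns where both
#' sequences carry an unambiguous base (A/C/G/T); gaps and IUPAC ambiguity
#' codes are excluded pairwise. The distance is `sqrt(1 - identity)` with
#' identity the fraction of matching valid sites, i.e. the square root of
#' the pairwise identity distance. No multiple-hit correction is applied.
#'
#' @param alignment An `alignment` (named character vector of equal-length
#'   sequences, see [read_fasta_alignment()]).
#' @return A symmetric `n x n` matrix of class `dist_matrix` with zero
#'   diagonal and the sequence ids as dimnames.
#' @export
identity_distance <- function(alignment) {
  seqs <- unclass(alignment)
  n <- length(seqs)
  if (n < 2L) stop_ctx("need >= 2 sequences")
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  valid <- chars %in% c("A", "C", "G", "T")
  dim(valid) <- dim(chars)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- valid[i, ] & valid[j, ]
    nv <- sum(ok)
    if (nv == 0)
      stop_ctx("no valid sites shared by '", names(seqs)[i], "' and '",
               names(seqs)[j], "'")
    ident <- sum(chars[i, ok] == chars[j, ok]) / nv
    d[i, j] <- d[j, i] <- sqrt(1 - ident)
  }
  as_dist_matrix(d)
}

#' Validate / construct a distance matrix
#'
#' @param d Symmetric non-negative numeric matrix with zero diagonal.
#' @return `d` with class `dist_matrix`.
#' @export
as_dist_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop_ctx("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-12) stop_ctx("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop_ctx("distance matrix diagonal must be zero")
  if (any(d < 0)) stop_ctx("distances must be non-negative")
  class(d) <- c("dist_matrix", class(unclass(d)))
  d
}

#' Cailliez additive constant
#'
#' The smallest constant `c*` such that adding it to every off-diagonal
#' dissimilarity makes the matrix Euclidean (all eigenvalues of the
#' double-centred Gram matrix non-negative). Computed as the largest real
#' eigenvalue of the `2n x 2n` block matrix
#' `[[0, 2*D1], [-I, -4*D2]]` with `D1 = -J D^2 J / 2`, `D2 = -J D J / 2`
#' and `J` the centring projector, clipped at zero.
#'
#' @param d A [as_dist_matrix()] matrix, `n >= 3`.
#' @return Non-negative scalar.
#' @export
cailliez_constant <- function(d) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  if (n < 3L) stop_ctx("Cailliez constant needs n >= 3")
  j <- diag(n) - matrix(1 / n, n, n)
  d1 <- -0.5 * j %*% (unclass(d)^2) %*% j
  d2 <- -0.5 * j %*% unclass(d) %*% j
  blk <- rbind(cbind(matrix(0, n, n), 2 * d1),
               cbind(-diag(n), -4 * d2))
  ev <- eigen(blk, only.values = TRUE)$values
  re <- Re(ev[abs(Im(ev)) < 1e-8 * max(1, abs(ev))])
  max(0, max(re))
}

#' Add the Cailliez constant to a dissimilarity matrix
#'
#' Off-diagonal entries are increased by [cailliez_constant()]; the diagonal
#' stays zero. The result has a positive semi-definite double-centred Gram
#' matrix, so classical MDS embeds it without negative eigenvalues.
#'
#' @param d A [as_dist_matrix()] matrix.
#' @return The corrected `dist_matrix`, with the constant in attribute
#'   `"cailliez"`.
#' @export
apply_cailliez <- function(d) {
  d <- as_dist_matrix(d)
  cc <- cailliez_constant(d)
  out <- unclass(d) + cc
  diag(out) <- 0
  out <- as_dist_matrix(out)
  attr(out, "cailliez") <- cc
  out
}

#' Write / read a distance matrix as a delimited table
#' @param d A `dist_matrix`.
#' @param path Output path.
#' @return `path` (write) or the `dist_matrix` (read).
#' @export
write_dist_matrix <- function(d, path) {
  utils::write.table(as.data.frame(unclass(d)), path, sep = ",",
                     quote = FALSE, row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  as_dist_matrix(m)
}
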