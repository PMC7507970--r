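#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 sum_j p_j (1 - p_j))` with `Z` the dosage matrix centered
#' by twice the counted-allele frequency.  Frequencies default to the
#' individuals in `genos` (i.e. everyone entering the analysis at hand);
#' a different frequency source can be supplied for scheme experiments.
#'
#' @param genos a [genotype_matrix] without missing calls (impute first)
#' @param freq optional per-marker frequencies of the counted allele used
#'   for centering and the denominator; defaults to the frequencies in
#'   `genos`.
#' @return a `grm` object: list with `matrix` (n x n, dimnames = ids),
#'   `denominator`, `ids` and `pop`.
#' @export
make_grm <- function(genos, freq = NULL) {
  d <- genos$dosages
  if (anyNA(d)) stop("missing dosages; run impute_missing() first")
  p <- if (is.null(freq)) colMeans(d) / 2 else freq
  if (length(p) != ncol(d)) stop("freq length does not match marker count")
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: zero GRM denominator")
  z <- sweep(d, 2, 2 * p)
  g <- tcrossprod(z) / denom
  dimnames(g) <- list(genos$ids, genos$ids)
  structure(list(matrix = g, denominator = denom, ids = genos$ids,
                 pop = genos$pop), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("genomic relationship matrix:", length(x$ids), "individuals,",
      sprintf("mean diagonal = %.3f\n", mean(diag(x$matrix))))
  invisible(x)
}

#' Principal components of a genomic relationship matrix
#'
#' Top-k eigenpairs of `G` in descending eigenvalue order.  Variance
#' explained is `lambda_i / sum(lambda)` with negative eigenvalues floored
#' at zero in the denominator.  Each eigenvector is oriented so that its
#' largest-magnitude loading is positive.
#'
#' @param grm a [make_grm] result (or a symmetric matrix)
#' @param k number of components
#' @return list with `vectors` (n x k), `values` (length k) and
#'   `variance_explained` (length k).
#' @export
pca_grm <- function(grm, k = 3) {
  g <- if (inherits(grm, "grm")) grm$matrix else as.matrix(grm)
  if (k > nrow(g)) stop("k exceeds the matrix dimension")
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  tot <- sum(pmax(e$values, 0))
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  rownames(vec) <- rownames(g)
  list(vectors = vec, values = e$values[seq_len(k)],
       variance_explained = pmax(e$values[seq_len(k)], 0) / tot)
}
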