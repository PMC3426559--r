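#' Standardize a genotype matrix for PCA
#'
#' Converts reference-allele counts to the smartpca-style standardized matrix
#' Y: for locus l with estimated reference-allele frequency
#' \eqn{\hat p_l} (the mean of non-missing genotypes divided by 2), each
#' non-missing entry c becomes \eqn{(c - 2\hat p_l)/\sqrt{2\hat p_l(1-\hat
#' p_l)}}. Monomorphic loci (\eqn{\hat p_l \in \{0, 1\}}, where the formula
#' is undefined) have their whole column set to zero, and entries at missing
#' genotypes are set to zero as well, so every column of Y has exactly zero
#' mean.
#'
#' @param G A [genotype_matrix()].
#' @return An object of class `standardized_matrix`: `values` (n x L real
#'   matrix Y), `allele_freqs` (length-L \eqn{\hat p}), `monomorphic_mask`
#'   (length-L logical), plus the individual/locus ids and population map
#'   carried over from `G`.
#' @export
standardize_genotypes <- function(G) {
  C <- G$values
  p_hat <- colMeans(C, na.rm = TRUE) / 2
  # loci with no observed genotypes at all are treated as monomorphic
  p_hat[is.nan(p_hat)] <- 0
  mono <- p_hat <= 0 | p_hat >= 1

  denom <- sqrt(2 * p_hat * (1 - p_hat))
  denom[mono] <- 1                         # avoid 0/0; columns zeroed below
  Y <- sweep(C, 2, 2 * p_hat, "-")
  Y <- sweep(Y, 2, denom, "/")
  Y[G$missing] <- 0
  Y[, mono] <- 0
  dimnames(Y) <- dimnames(C)

  structure(
    list(values = Y,
         allele_freqs = p_hat,
         monomorphic_mask = mono,
         individual_ids = G$individual_ids,
         population_of = G$population_of,
         locus_ids = G$locus_ids),
    class = "standardized_matrix")
}

#' Principal components of a standardized genotype matrix
#'
#' Eigen-decomposes the n x n matrix \eqn{YY^T} and reports the first n-1
#' components (the standardized matrix has rank at most n-1 because its
#' columns sum to zero). The k-th PC scores are \eqn{\sqrt{\lambda_k} u_k},
#' so the variance of score column k is \eqn{\lambda_k / n} and the map
#' reflects the relative variance carried by each axis — unlike
#' equal-variance eigenvector plotting. The proportion of variance explained
#' by PC k is \eqn{\lambda_k / \sum_{j=1}^{n-1} \lambda_j}.
#'
#' @param S A `standardized_matrix` from [standardize_genotypes()].
#' @return An object of class `pca_result`: `scores` (n x (n-1), columns
#'   named PC1..), `eigenvalues` (non-increasing, length n-1),
#'   `variance_explained` (sums to 1), `individual_ids`, `population_of`.
#' @export
run_pca <- function(S) {
  Y <- S$values
  n <- nrow(Y)
  if (n < 2L) stop("PCA needs at least 2 individuals")
  if (all(S$monomorphic_mask))
    stop("all loci are monomorphic; PCA is undefined")

  M <- tcrossprod(Y)                       # n x n, Y Y^T
  eig <- eigen(M, symmetric = TRUE)
  lambda <- eig$values[seq_len(n - 1L)]
  U <- eig$vectors[, seq_len(n - 1L), drop = FALSE]

  if (any(lambda < -1e-8 * max(lambda[1L], .Machine$double.eps)))
    stop("eigen decomposition produced a substantially negative eigenvalue")
  lambda[lambda < 0] <- 0

  scores <- sweep(U, 2, sqrt(lambda), "*")
  dimnames(scores) <- list(S$individual_ids,
                           paste0("PC", seq_len(n - 1L)))
  total <- sum(lambda)
  if (total <= 0) stop("standardized matrix has zero total variance")

  structure(
    list(scores = scores,
         eigenvalues = lambda,
         variance_explained = lambda / total,
         individual_ids = S$individual_ids,
         population_of = S$population_of),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat("pca_result: ", nrow(x$scores), " individuals, ",
      length(x$eigenvalues), " components\n", sep = "")
  cat("variance explained (top ", k, "): ",
      paste(sprintf("%.2f%%", 100 * x$variance_explained[seq_len(k)]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Standardize and run PCA in one step
#'
#' @param G A [genotype_matrix()].
#' @return A `pca_result`.
#' @export
genotype_pca <- function(G) run_pca(standardize_genotypes(G))
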