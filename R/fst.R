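#' Multi-locus Weir-Cockerham FST
#'
#' Moment estimator of FST from the 1984 variance-component framework, in
#' its genotypic form: per locus, the among-population (a), between
#' individuals within populations (b), and within-individual (c) components
#' are computed from per-population sample sizes, reference-allele
#' frequencies and observed heterozygote frequencies (no Hardy-Weinberg
#' assumption), and the overall estimate combines loci as a ratio of sums,
#' \eqn{\hat\theta = \sum_l a_l / \sum_l (a_l + b_l + c_l)} — not a mean of
#' per-locus ratios.
#'
#' Loci are excluded from both sums when their components are undefined:
#' fewer than two populations with data, average sample size of one, or
#' monomorphic across all populations. Negative estimates are reported as
#' computed.
#'
#' @param G A [genotype_matrix()] with at least 2 populations.
#' @return An object of class `fst_estimate`: `theta`,
#'   `per_locus_components` (L x 3 matrix of a, b, c; `NA` rows for
#'   excluded loci), `n_pops`, `loci_used`.
#' @export
weir_cockerham_fst <- function(G) {
  pop <- factor(G$population_of, levels = unique(G$population_of))
  r_tot <- nlevels(pop)
  if (r_tot < 2L) stop("FST needs at least 2 populations")

  V <- G$values
  obs <- !G$missing
  Vz <- V; Vz[!obs] <- 0L

  # per-population, per-locus tallies (r x L)
  n_mat <- rowsum(obs + 0L, pop)                  # genotyped individuals
  sum_mat <- rowsum(Vz, pop)                      # sum of allele counts
  het_mat <- rowsum((V == 1L & obs) + 0L, pop)    # heterozygote counts

  with_data <- n_mat > 0L
  r_l <- colSums(with_data)
  n_sum <- colSums(n_mat)                         # sum n_i
  n_sq_sum <- colSums(n_mat^2)

  p_mat <- ifelse(with_data, sum_mat / (2 * pmax(n_mat, 1L)), 0)
  h_mat <- ifelse(with_data, het_mat / pmax(n_mat, 1L), 0)

  n_bar <- n_sum / pmax(r_l, 1L)
  p_bar <- colSums(n_mat * p_mat) / pmax(n_sum, 1L)
  h_bar <- colSums(n_mat * h_mat) / pmax(n_sum, 1L)

  dev <- sweep(p_mat, 2, p_bar)
  s2 <- colSums(n_mat * dev^2) / (pmax(r_l - 1L, 1L) * pmax(n_bar, 1))
  n_c <- (n_sum - n_sq_sum / pmax(n_sum, 1L)) / pmax(r_l - 1L, 1L)

  usable <- r_l >= 2L & n_bar > 1 & p_bar > 0 & p_bar < 1 & n_c > 0

  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r_l - 1) / pmax(r_l, 1L) * s2 -
             h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r_l - 1) / pmax(r_l, 1L) * s2 -
       (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  c_comp <- h_bar / 2

  comp <- cbind(a = a, b = b, c = c_comp)
  comp[!usable, ] <- NA_real_
  rownames(comp) <- G$locus_ids

  denom <- sum(comp[usable, ], na.rm = TRUE)
  if (!any(usable)) stop("no locus is polymorphic with usable sample sizes")
  if (denom == 0) stop("total variance component is zero")

  structure(
    list(theta = sum(comp[usable, "a"]) / denom,
         per_locus_components = comp,
         n_pops = r_tot,
         loci_used = sum(usable)),
    class = "fst_estimate")
}

#' @export
print.fst_estimate <- function(x, ...) {
  cat(sprintf("fst_estimate: theta = %.5f (%d populations, %d loci used)\n",
              x$theta, x$n_pops, x$loci_used))
  invisible(x)
}
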