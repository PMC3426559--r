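# Permutation significance, leave-one-out population exclusion, and
# marker-count robustness for the genes-vs-geography Procrustes score.

# all permutations of 1..k as a k! x k matrix (k <= 8 in exhaustive mode)
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(first) {
    rest <- matrix(seq_len(k)[-first][sub], nrow(sub), k - 1L)
    cbind(rep(first, nrow(sub)), rest)
  }))
}

#' Permutation test for the genes-vs-geography similarity
#'
#' Tests the null hypothesis that no geographic pattern exists in the
#' population structure. Each permutation shuffles the population-to-location
#' assignment (locations are permuted among populations, all individuals of a
#' population moving together), recomputes the Procrustes similarity t0
#' between the fixed PC1-PC2 map and the permuted geography, and counts
#' exceedances. The PCA itself is not recomputed: only geography is permuted.
#' The p-value estimate is M/N where M is the number of permutations with
#' t0 at least as large as the observed value, displayed as `< 1/N` when
#' M = 0.
#'
#' @param pc_scores n x 2 matrix of PC1-PC2 coordinates, rows aligned with
#'   `G$individual_ids`.
#' @param geo A [geo_table()] covering every population of `G`.
#' @param G The [genotype_matrix()] supplying population membership.
#' @param N Number of random permutations (default 100000). Ignored when
#'   `exhaustive = TRUE`.
#' @param seed Integer seed for the permutation draws.
#' @param allow_reflection Procrustes family setting, matching the observed
#'   statistic (default TRUE).
#' @param exhaustive Enumerate all K! location assignments instead of random
#'   sampling (allowed for up to 8 populations).
#' @return An object of class `permutation_result`: `t0_observed`, `null_t`,
#'   `N`, `exceed_count`, `p_value` (numeric M/N), `p_value_display`,
#'   `seed`, `exhaustive`.
#' @export
permutation_test <- function(pc_scores, geo, G, N = 100000L, seed = 1L,
                             allow_reflection = TRUE, exhaustive = FALSE) {
  Y <- as.matrix(pc_scores)[, 1:2, drop = FALSE]
  if (nrow(Y) != n_individuals(G))
    stop("pc_scores rows must align with G individuals")
  pops <- unique(G$population_of)
  K <- length(pops)
  if (K < 3L) stop("permutation test needs at least 3 populations")
  if (!exhaustive && N < 1L) stop("N must be at least 1")
  if (exhaustive && K > 8L)
    stop("exhaustive enumeration supported for at most 8 populations")

  idx <- match(geo$population, pops)
  if (!all(seq_len(K) %in% idx[!is.na(idx)]))
    stop("populations without coordinates: ",
         paste(setdiff(pops, geo$population), collapse = ", "))
  loc <- matrix(NA_real_, K, 2L)
  loc[idx[!is.na(idx)], ] <- cbind(geo$x, geo$y)[!is.na(idx), ]
  pop_idx <- match(G$population_of, pops)

  Yc <- sweep(Y, 2, colMeans(Y))
  trY <- sum(Yc^2)
  observed_X <- loc[pop_idx, , drop = FALSE]
  t0_one <- function(X) {
    Xc <- sweep(X, 2, colMeans(X))
    t0_stat(Xc, sum(Xc^2), Yc, trY, allow_reflection)
  }
  t0_obs <- t0_one(observed_X)

  if (exhaustive) {
    perms <- all_permutations(K)
    N <- nrow(perms)
    null_t <- vapply(seq_len(N), function(i)
      t0_one(loc[perms[i, ][pop_idx], , drop = FALSE]), numeric(1))
  } else {
    null_t <- with_seed(seed, {
      vapply(seq_len(N), function(i) {
        perm <- sample.int(K)
        t0_one(loc[perm[pop_idx], , drop = FALSE])
      }, numeric(1))
    })
  }

  M <- sum(null_t >= t0_obs)
  structure(
    list(t0_observed = t0_obs,
         null_t = null_t,
         N = as.integer(N),
         exceed_count = M,
         p_value = M / N,
         p_value_display = if (M == 0L) paste0("< ", format(1 / N))
                           else format(M / N),
         seed = seed,
         exhaustive = exhaustive),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: t0 = %.4f, p %s (%d/%d%s)\n",
              x$t0_observed,
              if (x$exceed_count == 0L) x$p_value_display
              else paste("=", x$p_value_display),
              x$exceed_count, x$N,
              if (x$exhaustive) ", exhaustive" else ""))
  invisible(x)
}

#' Leave-one-out population-exclusion analysis
#'
#' For each population in turn: drop its individuals from the post-QC
#' matrix, rerun standardization and PCA (the outlier search is not
#' repeated), and score the new PC1-PC2 map twice — against geography
#' (`t0_prime`) and against the original PC1-PC2 map restricted to the
#' common set of individuals (`t_pca`). A population whose position
#' contradicts its geography typically raises `t0_prime` above the
#' full-data t0 when excluded; a negligible population leaves `t_pca` near
#' 1.
#'
#' @param G Post-QC [genotype_matrix()] with at least 4 populations.
#' @param geo A [geo_table()].
#' @param allow_reflection Procrustes family setting (default TRUE).
#' @return A data.frame with one row per excluded population: columns
#'   `excluded_population`, `n_excluded`, `t0_prime`, `t_pca`,
#'   `reflection_used_geo`; attribute `t0_full` holds the full-data score.
#' @export
leave_one_out <- function(G, geo, allow_reflection = TRUE) {
  pops <- unique(G$population_of)
  if (length(pops) < 4L)
    stop("leave-one-out needs at least 4 populations")

  pca_full <- genotype_pca(G)
  coords_full <- expand_to_individuals(geo, G)
  t0_full <- procrustes_t0(coords_full, pca_full$scores[, 1:2],
                           allow_reflection)

  rows <- lapply(pops, function(pop) {
    keep <- G$population_of != pop
    if (sum(keep) < 3L)
      stop("excluding '", pop, "' leaves fewer than 3 individuals")
    Gr <- subset_individuals(G, keep)
    pca_r <- genotype_pca(Gr)
    fit_geo <- procrustes_fit(expand_to_individuals(geo, Gr),
                              pca_r$scores[, 1:2], allow_reflection)
    shared <- Gr$individual_ids           # all retained ids are shared
    t_pca <- procrustes_t0(pca_full$scores[shared, 1:2, drop = FALSE],
                           pca_r$scores[shared, 1:2, drop = FALSE],
                           allow_reflection)
    data.frame(excluded_population = pop,
               n_excluded = sum(!keep),
               t0_prime = fit_geo$t0,
               t_pca = t_pca,
               reflection_used_geo = fit_geo$reflection_used,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "t0_full") <- t0_full
  out
}

#' Similarity as a function of marker count
#'
#' For each requested marker count, subsamples that many loci (uniformly,
#' reproducibly from `seed`), reruns standardization, PCA and Procrustes
#' against geography, and records t0. Because the locus draw depends only on
#' `(seed, L_sub)` and the shared locus list, curves computed for different
#' datasets over the same loci use identical marker sets.
#'
#' @param G A post-QC [genotype_matrix()].
#' @param geo A [geo_table()].
#' @param L_values Increasing vector of marker counts, all at most
#'   `n_loci(G)`.
#' @param seed Integer seed for the locus draws.
#' @param allow_reflection Procrustes family setting (default TRUE).
#' @return A data.frame with columns `L` and `t0`; attribute `seed`.
#' @export
marker_curve <- function(G, geo, L_values, seed = 1L,
                         allow_reflection = TRUE) {
  L_values <- as.integer(L_values)
  if (any(L_values < 1L) || any(L_values > n_loci(G)))
    stop("L_values must lie in [1, n_loci(G)]")
  coords <- NULL
  t0s <- vapply(L_values, function(L_sub) {
    Gs <- subsample_loci(G, L_sub, seed)
    pca <- genotype_pca(Gs)
    if (is.null(coords)) coords <<- expand_to_individuals(geo, Gs)
    procrustes_t0(coords, pca$scores[, 1:2], allow_reflection)
  }, numeric(1))
  out <- data.frame(L = L_values, t0 = t0s)
  attr(out, "seed") <- seed
  out
}
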