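#' Remove individuals with high missing-data rates
#'
#' Drops every individual whose fraction of missing genotypes, computed over
#' all loci of the current matrix, is strictly greater than
#' `max_missing_fraction`. An individual with exactly the threshold fraction
#' is retained. The ordering of retained individuals is preserved.
#'
#' @param G A [genotype_matrix()].
#' @param max_missing_fraction Removal threshold, default 0.05.
#' @return A list with `genotypes` (the filtered matrix) and `removed`
#'   (character vector of removed individual ids, possibly empty).
#' @export
filter_missing_individuals <- function(G, max_missing_fraction = 0.05) {
  if (max_missing_fraction < 0 || max_missing_fraction >= 1)
    stop("max_missing_fraction must be in [0, 1)")
  frac <- rowMeans(G$missing)
  drop <- frac > max_missing_fraction
  if (all(drop)) stop("all individuals exceed the missing-data threshold")
  out <- if (any(drop)) subset_individuals(G, !drop) else G
  list(genotypes = out, removed = G$individual_ids[drop])
}

#' Iterative PCA-based outlier removal
#'
#' Repeatedly standardizes the matrix, runs PCA, and flags any individual
#' whose score on at least one of the top `min(n_pcs, n-1)` PCs lies more
#' than `sd_threshold` sample standard deviations from that PC's mean.
#' Flagged individuals are removed and the procedure repeats until a pass
#' flags nobody. The per-PC standard deviation is recomputed from the
#' current iteration's scores; the flagging decision is invariant to the
#' per-PC score scaling.
#'
#' @param G A [genotype_matrix()], normally already filtered by
#'   [filter_missing_individuals()].
#' @param sd_threshold Flagging threshold in standard deviations, default 10.
#' @param n_pcs Number of top PCs examined, default 10 (capped at n-1).
#' @return A list with `genotypes` (the cleaned matrix) and `report`, a
#'   `qc_report` holding `removed_outliers` (data.frame of iteration,
#'   individual_id) and `iterations` (number of passes, counting the final
#'   pass that flags nobody).
#' @export
iterative_outlier_removal <- function(G, sd_threshold = 10, n_pcs = 10L) {
  if (sd_threshold <= 0) stop("sd_threshold must be positive")
  removed <- data.frame(iteration = integer(), individual_id = character(),
                        stringsAsFactors = FALSE)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    n <- n_individuals(G)
    pca <- genotype_pca(G)
    k <- min(n_pcs, n - 1L)
    sc <- pca$scores[, seq_len(k), drop = FALSE]
    mu <- colMeans(sc)
    sdv <- apply(sc, 2, stats::sd)
    sdv[sdv == 0] <- Inf                  # constant PC flags nobody
    z <- abs(sweep(sweep(sc, 2, mu, "-"), 2, sdv, "/"))
    flag <- apply(z > sd_threshold, 1, any)
    if (!any(flag)) break
    if (n - sum(flag) < 3L)
      stop("outlier removal would leave fewer than 3 individuals")
    removed <- rbind(removed,
                     data.frame(iteration = iter,
                                individual_id = G$individual_ids[flag],
                                stringsAsFactors = FALSE))
    G <- subset_individuals(G, !flag)
  }
  list(genotypes = G,
       report = structure(list(removed_outliers = removed,
                               iterations = iter),
                          class = "qc_report"))
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report: ", nrow(x$removed_outliers), " outlier(s) removed in ",
      x$iterations, " pass(es)\n", sep = "")
  invisible(x)
}

#' Full quality-control pipeline
#'
#' Missing-data filtering followed by iterative PCA-outlier removal, in that
#' order. Running the pair a second time on its own output changes nothing.
#'
#' @inheritParams filter_missing_individuals
#' @inheritParams iterative_outlier_removal
#' @return A list with `genotypes`, `removed_high_missing`,
#'   `removed_outliers` (data.frame), and `iterations`.
#' @export
run_qc <- function(G, max_missing_fraction = 0.05, sd_threshold = 10,
                   n_pcs = 10L) {
  mm <- filter_missing_individuals(G, max_missing_fraction)
  ol <- iterative_outlier_removal(mm$genotypes, sd_threshold, n_pcs)
  list(genotypes = ol$genotypes,
       removed_high_missing = mm$removed,
       removed_outliers = ol$report$removed_outliers,
       iterations = ol$report$iterations)
}
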