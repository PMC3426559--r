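#' Run a complete regional genes-vs-geography analysis
#'
#' Orchestrates the full per-region pipeline: missing-data filter,
#' iterative PCA-outlier removal, standardization, PCA, geographic
#' projection, Procrustes superposition of the PC1-PC2 map on geography, a
#' permutation test, and optional leave-one-out, marker-curve and FST
#' stages. Every reported number equals the value obtained by calling the
#' corresponding stage function directly.
#'
#' @param G A [genotype_matrix()] (use [load_genotype_matrix()] for files).
#' @param geo A [geo_table()] of population coordinates.
#' @param projection `"unprojected"` (planar longitude/latitude, used for
#'   regional analyses) or `"gall_peters"` (worldwide: Americas shift then
#'   equal-area projection).
#' @param shift_threshold Longitude threshold for the Americas shift when
#'   `projection = "gall_peters"`, default -40.
#' @param max_missing_fraction Missing-data removal threshold, default 0.05.
#' @param outlier_sd,outlier_pcs Iterative outlier-removal settings,
#'   defaults 10 and 10.
#' @param n_permutations Permutations for the significance test, default
#'   100000 in line with the full-scale convention; reduce for exploratory
#'   runs.
#' @param seed Integer seed governing the permutation draws and any marker
#'   subsampling.
#' @param run_leave_one_out Run the population-exclusion analysis
#'   (needs >= 4 populations), default FALSE.
#' @param marker_L Optional vector of marker counts for a robustness curve.
#' @param run_fst Estimate multi-locus Weir-Cockerham FST, default TRUE.
#' @param allow_reflection Procrustes family setting, default TRUE.
#' @param out_dir Optional directory; when given, the report is written as
#'   `report.json` plus TSVs for PC scores and any leave-one-out /
#'   marker-curve tables.
#' @return An object of class `region_report`: sample accounting
#'   (`n_initial`, `n_after_qc`, removed ids), `variance_explained_pc1`/
#'   `_pc2` (percent), `t0`, `rotation_deg`, `reflection_used`,
#'   `p_value`, `p_value_display`, `fst_percent`, and the underlying stage
#'   objects (`pca`, `procrustes`, `permutation`, `leave_one_out`,
#'   `marker_curve`, `fst`).
#' @export
run_region_analysis <- function(G, geo,
                                projection = c("unprojected", "gall_peters"),
                                shift_threshold = -40,
                                max_missing_fraction = 0.05,
                                outlier_sd = 10, outlier_pcs = 10L,
                                n_permutations = 100000L, seed = 1L,
                                run_leave_one_out = FALSE,
                                marker_L = NULL,
                                run_fst = TRUE,
                                allow_reflection = TRUE,
                                out_dir = NULL) {
  projection <- match.arg(projection)
  n_initial <- n_individuals(G)

  qc <- run_qc(G, max_missing_fraction, outlier_sd, outlier_pcs)
  Gq <- qc$genotypes

  if (projection == "gall_peters")
    geo <- gall_peters_project(shift_americas(geo, shift_threshold))

  pca <- genotype_pca(Gq)
  coords <- expand_to_individuals(geo, Gq)
  fit <- procrustes_fit(coords, pca$scores[, 1:2], allow_reflection)
  perm <- permutation_test(pca$scores[, 1:2], geo, Gq,
                           N = n_permutations, seed = seed,
                           allow_reflection = allow_reflection)

  loo <- if (run_leave_one_out) leave_one_out(Gq, geo, allow_reflection)
  curve <- if (!is.null(marker_L))
    marker_curve(Gq, geo, marker_L, seed, allow_reflection)
  fst <- if (run_fst) weir_cockerham_fst(Gq)

  report <- structure(
    list(n_initial = n_initial,
         n_after_qc = n_individuals(Gq),
         removed_high_missing = qc$removed_high_missing,
         removed_outliers = qc$removed_outliers,
         qc_iterations = qc$iterations,
         projection = projection,
         variance_explained_pc1 = 100 * pca$variance_explained[1L],
         variance_explained_pc2 = 100 * pca$variance_explained[2L],
         t0 = fit$t0,
         rotation_deg = fit$rotation_deg,
         reflection_used = fit$reflection_used,
         p_value = perm$p_value,
         p_value_display = perm$p_value_display,
         fst_percent = if (run_fst) 100 * fst$theta else NA_real_,
         seed = seed,
         pca = pca, procrustes = fit, permutation = perm,
         leave_one_out = loo, marker_curve = curve, fst = fst),
    class = "region_report")

  if (!is.null(out_dir)) write_region_report(report, Gq, out_dir)
  report
}

#' @export
print.region_report <- function(x, ...) {
  cat("region_report\n")
  cat(sprintf("  individuals: %d -> %d after QC (%d high-missing, %d outliers in %d pass(es))\n",
              x$n_initial, x$n_after_qc, length(x$removed_high_missing),
              nrow(x$removed_outliers), x$qc_iterations))
  cat(sprintf("  variance explained: PC1 %.2f%%, PC2 %.2f%% (%s)\n",
              x$variance_explained_pc1, x$variance_explained_pc2,
              x$projection))
  cat(sprintf("  Procrustes t0 = %.3f, rotation %.2f deg CCW%s, p %s\n",
              x$t0, x$rotation_deg,
              if (x$reflection_used) " (reflected)" else "",
              if (x$p_value == 0) x$p_value_display
              else paste("=", x$p_value_display)))
  if (!is.na(x$fst_percent))
    cat(sprintf("  FST = %.3f%%\n", x$fst_percent))
  invisible(x)
}

write_region_report <- function(report, Gq, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary_fields <- c("n_initial", "n_after_qc", "removed_high_missing",
                      "qc_iterations", "projection",
                      "variance_explained_pc1", "variance_explained_pc2",
                      "t0", "rotation_deg", "reflection_used",
                      "p_value", "p_value_display", "fst_percent", "seed")
  js <- report[summary_fields]
  js$removed_outliers <- report$removed_outliers
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  scores <- data.frame(individual_id = rownames(report$pca$scores),
                       population = unname(Gq$population_of),
                       report$pca$scores[, 1:2, drop = FALSE])
  utils::write.table(scores, file.path(out_dir, "pc_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$leave_one_out))
    utils::write.table(report$leave_one_out,
                       file.path(out_dir, "leave_one_out.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$marker_curve))
    utils::write.table(report$marker_curve,
                       file.path(out_dir, "marker_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
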