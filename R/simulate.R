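#' Configuration for the isolation-by-distance lattice simulator
#'
#' Describes a set of populations at known planar locations whose allele
#' frequencies are spatially autocorrelated: nearby populations are more
#' similar than distant ones, the statistical signature the
#' genes-vs-geography pipeline is designed to detect.
#'
#' @param grid Data.frame with columns `population`, `latitude`,
#'   `longitude` (degrees), or a K x 2 matrix of (longitude, latitude)
#'   pairs which will be labelled pop1..popK.
#' @param n_per_pop Individuals sampled per population.
#' @param L Number of loci.
#' @param ancestral_freq_range Interval for the per-locus ancestral
#'   reference-allele frequency, default (0.1, 0.9).
#' @param spatial_sd Standard deviation (logit scale) of the spatially
#'   correlated per-population frequency deviation; 0 gives a panmictic
#'   null with no structure.
#' @param spatial_range Correlation length rho (degrees) of the exponential
#'   spatial covariance `spatial_sd^2 * exp(-d / rho)`.
#' @param missing_rate Probability that any genotype is missing.
#' @param n_outlier_individuals Number of planted outlier individuals (taken
#'   from the first population(s), one per individual slot).
#' @param outlier_shift Mixing weight in \[0, 1\] pulling each outlier's
#'   allele frequencies toward independent uniform frequencies.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(grid, n_per_pop, L,
                       ancestral_freq_range = c(0.1, 0.9),
                       spatial_sd = 1, spatial_range = 30,
                       missing_rate = 0,
                       n_outlier_individuals = 0L, outlier_shift = 0,
                       seed = 1L) {
  if (is.matrix(grid))
    grid <- data.frame(population = paste0("pop", seq_len(nrow(grid))),
                       longitude = grid[, 1L], latitude = grid[, 2L],
                       stringsAsFactors = FALSE)
  stopifnot(nrow(grid) >= 1L, n_per_pop >= 1L, L >= 1L,
            length(ancestral_freq_range) == 2L,
            ancestral_freq_range[1L] > 0, ancestral_freq_range[2L] < 1,
            spatial_sd >= 0, spatial_range > 0,
            missing_rate >= 0, missing_rate <= 1,
            outlier_shift >= 0, outlier_shift <= 1)
  structure(list(grid = grid, n_per_pop = as.integer(n_per_pop),
                 L = as.integer(L),
                 ancestral_freq_range = ancestral_freq_range,
                 spatial_sd = spatial_sd, spatial_range = spatial_range,
                 missing_rate = missing_rate,
                 n_outlier_individuals = as.integer(n_outlier_individuals),
                 outlier_shift = outlier_shift,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' A rectangular lattice of population locations
#'
#' @param nx,ny Grid dimensions.
#' @param spacing Degrees between adjacent grid points, default 10.
#' @param origin Longitude/latitude of the lower-left corner.
#' @return Data.frame with `population`, `longitude`, `latitude`.
#' @export
lattice_grid <- function(nx, ny, spacing = 10, origin = c(0, 0)) {
  g <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  data.frame(population = sprintf("pop_%d_%d", g$ix + 1L, g$iy + 1L),
             longitude = origin[1L] + g$ix * spacing,
             latitude = origin[2L] + g$iy * spacing,
             stringsAsFactors = FALSE)
}

draw_genotypes <- function(freq_rows) {
  # freq_rows: n x L matrix of per-individual allele frequencies
  n <- nrow(freq_rows); L <- ncol(freq_rows)
  matrix(stats::rbinom(n * L, 2L, freq_rows), n, L)
}

#' Simulate an isolation-by-distance dataset on a lattice
#'
#' Per locus, an ancestral reference-allele frequency is drawn uniformly
#' from `ancestral_freq_range`; per-population deviations on the logit
#' scale come from a zero-mean Gaussian process over the population
#' locations with covariance `spatial_sd^2 * exp(-d / spatial_range)`
#' (d = planar distance in degrees, treating 1 degree latitude = 1 degree
#' longitude). Population frequencies are clipped to \[0.001, 0.999\]
#' (monomorphic columns may still arise by sampling); individual genotypes
#' are Binomial(2, p). Missingness is uniform. Planted outlier individuals
#' have their frequencies mixed toward independent uniform frequencies by
#' `outlier_shift`. The same configuration always yields the identical
#' dataset.
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_dataset`: `genotypes`
#'   ([genotype_matrix()]), `geo` ([geo_table()] of true locations),
#'   `true_freqs` (K x L), `outlier_ids`, `config`.
#' @export
simulate_lattice_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- config$grid
  K <- nrow(grid); L <- config$L; n_pp <- config$n_per_pop

  with_seed(config$seed, {
    anc <- stats::runif(L, config$ancestral_freq_range[1L],
                        config$ancestral_freq_range[2L])
    if (config$spatial_sd > 0 && K > 1L) {
      d <- as.matrix(stats::dist(cbind(grid$longitude, grid$latitude)))
      Sigma <- config$spatial_sd^2 * exp(-d / config$spatial_range)
      # jitter keeps the Cholesky stable when populations nearly coincide
      Lchol <- t(chol(Sigma + diag(1e-10, K)))
      Z <- Lchol %*% matrix(stats::rnorm(K * L), K, L)
    } else {
      Z <- matrix(0, K, L)
    }
    logit_p <- sweep(Z, 2, stats::qlogis(anc), "+")
    p_pop <- pmin(pmax(stats::plogis(logit_p), 0.001), 0.999)

    pop_of_ind <- rep(seq_len(K), each = n_pp)
    freq_rows <- p_pop[pop_of_ind, , drop = FALSE]

    outlier_ids <- character(0)
    if (config$n_outlier_individuals > 0L) {
      take <- seq_len(min(config$n_outlier_individuals, nrow(freq_rows)))
      for (i in take) {
        u <- stats::runif(L)
        freq_rows[i, ] <- (1 - config$outlier_shift) * freq_rows[i, ] +
          config$outlier_shift * u
      }
      outlier_ids <- take
    }

    values <- draw_genotypes(freq_rows)
    if (config$missing_rate > 0) {
      mask <- matrix(stats::runif(length(values)) < config$missing_rate,
                     nrow(values))
      values[mask] <- NA_integer_
    }

    ind_ids <- sprintf("%s_i%02d", grid$population[pop_of_ind],
                       sequence(rep(n_pp, K)))
    popmap <- stats::setNames(grid$population[pop_of_ind], ind_ids)
    G <- genotype_matrix(values, individual_ids = ind_ids,
                         population_of = popmap,
                         locus_ids = paste0("L", seq_len(L)))
    structure(
      list(genotypes = G,
           geo = geo_table(grid$population, grid$latitude, grid$longitude),
           true_freqs = p_pop,
           outlier_ids = if (length(outlier_ids)) ind_ids[outlier_ids]
                         else character(0),
           config = config),
      class = "synthetic_dataset")
  })
}

#' Simulate genotypes under the Balding-Nichols model
#'
#' Per locus, an ancestral frequency p is drawn from Uniform(0.1, 0.9) and
#' each of `r` populations receives an independent frequency from
#' Beta(p(1-F)/F, (1-p)(1-F)/F), whose expectation is p and whose
#' among-population variance is F p(1-p) — so F is the simulation's true
#' FST. Genotypes are Binomial(2, p_pop). Populations are placed at
#' arbitrary distinct locations on a circle (geography carries no signal
#' under this model).
#'
#' @param F_st Differentiation parameter in (0, 1).
#' @param r Number of populations.
#' @param n Individuals per population.
#' @param L Number of loci.
#' @param seed Integer seed.
#' @return A `synthetic_dataset` (see [simulate_lattice_dataset()]).
#' @export
simulate_balding_nichols <- function(F_st, r, n, L, seed = 1L) {
  if (F_st <= 0 || F_st >= 1) stop("F_st must be in (0, 1)")
  with_seed(seed, {
    anc <- stats::runif(L, 0.1, 0.9)
    shape_mult <- (1 - F_st) / F_st
    p_pop <- matrix(stats::rbeta(r * L,
                                 rep(anc * shape_mult, each = r),
                                 rep((1 - anc) * shape_mult, each = r)),
                    r, L)
    pop_of_ind <- rep(seq_len(r), each = n)
    values <- draw_genotypes(p_pop[pop_of_ind, , drop = FALSE])

    ang <- 2 * pi * (seq_len(r) - 1L) / r
    grid <- data.frame(population = paste0("pop", seq_len(r)),
                       longitude = 30 * cos(ang), latitude = 30 * sin(ang),
                       stringsAsFactors = FALSE)
    ind_ids <- sprintf("pop%d_i%03d", pop_of_ind, sequence(rep(n, r)))
    popmap <- stats::setNames(grid$population[pop_of_ind], ind_ids)
    G <- genotype_matrix(values, individual_ids = ind_ids,
                         population_of = popmap,
                         locus_ids = paste0("L", seq_len(L)))
    structure(
      list(genotypes = G,
           geo = geo_table(grid$population, grid$latitude, grid$longitude),
           true_freqs = p_pop,
           outlier_ids = character(0),
           config = list(F_st = F_st, r = r, n = n, L = L, seed = seed)),
      class = "synthetic_dataset")
  })
}

#' Write a synthetic dataset as the canonical TSV trio
#'
#' Emits the genotype TSV, population map and coordinate table consumed by
#' [load_genotype_matrix()] and [read_geo_table()], plus the configuration
#' as JSON.
#'
#' @param sim A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(genotypes = file.path(dir, "genotypes.tsv"),
                popmap = file.path(dir, "popmap.tsv"),
                coords = file.path(dir, "coords.tsv"),
                config = file.path(dir, "config.json"))
  write_genotype_tsv(sim$genotypes, paths$genotypes, paths$popmap)
  utils::write.table(
    data.frame(population = sim$geo$population,
               latitude = sim$geo$latitude,
               longitude = sim$geo$longitude),
    paths$coords, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  if (inherits(cfg, "sim_config")) cfg <- unclass(cfg)
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
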