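#!/usr/bin/env Rscript

# Generate the synthetic study datasets used throughout the analysis:
#
#   strong  - 5x5 lattice, pronounced isolation by distance (FST ~ 10%),
#             the regime where PC maps mirror geography almost perfectly
#             (analogous to worldwide/continental sampling)
#   weak    - 4x4 lattice, subtle differentiation (FST ~ 0.2%), the regime
#             where geographic structure emerges only with many markers
#             (analogous to a single low-divergence region)
#   bn_F005 - Balding-Nichols panel with known truth F = 0.05 for FST
#             calibration
#
# Each dataset is written as the genotype TSV / population map / coordinate
# trio that the downstream scripts load back.

suppressPackageStartupMessages(library(genogeo))

out_root <- "results/data"
dir.create(out_root, showWarnings = FALSE, recursive = TRUE)

strong <- simulate_lattice_dataset(
  sim_config(lattice_grid(5, 5), n_per_pop = 10, L = 2000,
             spatial_sd = 1, spatial_range = 30,
             missing_rate = 0.01, seed = 20260901L))
write_synthetic_dataset(strong, file.path(out_root, "strong"))
cat("strong:", n_individuals(strong$genotypes), "individuals,",
    n_loci(strong$genotypes), "loci,",
    nrow(strong$geo), "populations\n")

weak <- simulate_lattice_dataset(
  sim_config(lattice_grid(4, 4), n_per_pop = 15, L = 20000,
             spatial_sd = 0.15, spatial_range = 30, seed = 20260902L))
write_synthetic_dataset(weak, file.path(out_root, "weak"))
cat("weak:", n_individuals(weak$genotypes), "individuals,",
    n_loci(weak$genotypes), "loci\n")

bn <- simulate_balding_nichols(0.05, r = 10, n = 30, L = 5000,
                               seed = 20260903L)
write_synthetic_dataset(bn, file.path(out_root, "bn_F005"))
cat("bn_F005:", n_individuals(bn$genotypes), "individuals,",
    n_loci(bn$genotypes), "loci (true F = 0.05)\n")
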