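structured_sim <- function(K = 6, n_per_pop = 5, L = 400, seed = 17,
                           grid = NULL) {
  if (is.null(grid)) grid <- irregular_grid(K, seed = seed + 500)
  simulate_lattice_dataset(
    sim_config(grid, n_per_pop = n_per_pop, L = L,
               spatial_sd = 1, spatial_range = 20, seed = seed))
}

test_that("exhaustive mode enumerates every location assignment", {
  sim <- structured_sim(K = 3, n_per_pop = 4, L = 200, seed = 2)
  pca <- genotype_pca(sim$genotypes)
  res <- permutation_test(pca$scores[, 1:2], sim$geo, sim$genotypes,
                          exhaustive = TRUE)
  expect_identical(res$N, 6L)           # 3! assignments
  expect_true(all(res$null_t >= 0 & res$null_t <= 1))
  # identity assignment is in the enumeration, so M >= 1 always
  expect_gte(res$exceed_count, 1L)
  expect_true(any(abs(res$null_t - res$t0_observed) < 1e-12))

  # random sampling from the same 6 assignments can only produce values
  # from the exhaustive set
  res_r <- permutation_test(pca$scores[, 1:2], sim$geo, sim$genotypes,
                            N = 50, seed = 3)
  expect_true(all(vapply(res_r$null_t, function(t)
    min(abs(t - res$null_t)) < 1e-12, logical(1))))
})

test_that("perfect geographic scores give t0 = 1 with ties counted as exceedances", {
  sim <- structured_sim(K = 4, n_per_pop = 3, L = 100, seed = 6)
  coords <- expand_to_individuals(sim$geo, sim$genotypes)
  res <- permutation_test(coords, sim$geo, sim$genotypes, exhaustive = TRUE)
  expect_equal(res$t0_observed, 1, tolerance = 1e-12)
  expect_identical(res$N, 24L)
  # only permutations that also reach 1 count; identity always does
  expect_identical(res$exceed_count,
                   sum(res$null_t > 1 - 1e-12))
})

test_that("p-value display follows the M/N convention with < 1/N at zero", {
  sim <- structured_sim(K = 6, n_per_pop = 5, L = 600, seed = 17)
  pca <- genotype_pca(sim$genotypes)
  res <- permutation_test(pca$scores[, 1:2], sim$geo, sim$genotypes,
                          N = 99, seed = 10)
  if (res$exceed_count == 0L) {
    expect_match(res$p_value_display, "^< ")
    expect_equal(res$p_value, 0)
  } else {
    expect_equal(res$p_value, res$exceed_count / res$N)
  }
  expect_error(permutation_test(pca$scores[, 1:2], sim$geo, sim$genotypes,
                                N = 0, seed = 1), "N must be")
})

test_that("permutation draws are reproducible from the seed", {
  sim <- structured_sim(K = 5, n_per_pop = 4, L = 300, seed = 9)
  pca <- genotype_pca(sim$genotypes)
  r1 <- permutation_test(pca$scores[, 1:2], sim$geo, sim$genotypes,
                         N = 200, seed = 42)
  r2 <- permutation_test(pca$scores[, 1:2], sim$geo, sim$genotypes,
                         N = 200, seed = 42)
  expect_identical(r1$null_t, r2$null_t)
  expect_identical(r1$exceed_count, r2$exceed_count)
})

test_that("the permutation null is exchangeable across seeds", {
  sim <- structured_sim(K = 7, n_per_pop = 4, L = 300, seed = 23)
  pca <- genotype_pca(sim$genotypes)
  n1 <- permutation_test(pca$scores[, 1:2], sim$geo, sim$genotypes,
                         N = 400, seed = 1)$null_t
  n2 <- permutation_test(pca$scores[, 1:2], sim$geo, sim$genotypes,
                         N = 400, seed = 2)$null_t
  expect_gt(suppressWarnings(stats::ks.test(n1, n2)$p.value), 0.01)
})

test_that("leave-one-out aligns shared individuals and tracks geography", {
  sim <- structured_sim(K = 6, n_per_pop = 5, L = 500, seed = 17)
  loo <- leave_one_out(sim$genotypes, sim$geo)
  expect_identical(nrow(loo), 6L)
  expect_true(all(loo$t0_prime >= 0 & loo$t0_prime <= 1))
  expect_true(all(loo$t_pca >= 0 & loo$t_pca <= 1))
  expect_identical(loo$n_excluded, rep(5L, 6L))
  expect_true(is.numeric(attr(loo, "t0_full")))
})

test_that("excluding a geographically discordant population raises t0", {
  # a population placed (geographically) far from its genetic neighbours:
  # simulate on a line, then corrupt one population's map position
  grid <- data.frame(population = paste0("p", 1:6),
                     longitude = c(0, 10, 20, 30, 40, 50),
                     latitude = c(0, 6, 2, 8, 4, 10))
  sim <- simulate_lattice_dataset(
    sim_config(grid, n_per_pop = 6, L = 800, spatial_sd = 1,
               spatial_range = 15, seed = 33))
  geo_bad <- sim$geo
  geo_bad$x[geo_bad$population == "p1"] <- 200   # planted discordance
  G <- sim$genotypes
  t0_full <- procrustes_t0(expand_to_individuals(geo_bad, G),
                           genotype_pca(G)$scores[, 1:2])
  loo <- leave_one_out(G, geo_bad)
  expect_gt(loo$t0_prime[loo$excluded_population == "p1"], t0_full)
})

test_that("excluding a one-individual population barely changes the PC map", {
  sim <- structured_sim(K = 6, n_per_pop = 5, L = 800, seed = 41)
  G <- sim$genotypes
  # shrink p6 to a single individual
  keep <- G$population_of != "p6" | G$individual_ids == "p6_i01"
  G1 <- subset_individuals(G, keep)
  loo <- leave_one_out(G1, sim$geo)
  expect_gt(loo$t_pca[loo$excluded_population == "p6"], 0.99)
})

test_that("marker curves end at the full-data t0 and share loci across calls", {
  sim <- structured_sim(K = 5, n_per_pop = 4, L = 400, seed = 29)
  G <- sim$genotypes
  full_t0 <- procrustes_t0(expand_to_individuals(sim$geo, G),
                           genotype_pca(G)$scores[, 1:2])
  mc <- marker_curve(G, sim$geo, c(100, 400), seed = 3)
  expect_identical(mc$L, c(100L, 400L))
  expect_equal(mc$t0[2], full_t0, tolerance = 1e-12)
  mc2 <- marker_curve(G, sim$geo, c(100, 400), seed = 3)
  expect_identical(mc$t0, mc2$t0)
  expect_error(marker_curve(G, sim$geo, c(100, 500), seed = 1), "L_values")
})
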