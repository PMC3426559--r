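test_that("genotype_matrix validates its invariants", {
  pm <- c(a = "p1", b = "p1", c = "p2")
  G <- genotype_matrix(matrix(c(0L, 1L, 2L, NA, 0L, 1L), 3, 2),
                       individual_ids = c("a", "b", "c"),
                       population_of = pm)
  expect_s3_class(G, "genotype_matrix")
  expect_identical(sum(G$missing), 1L)

  expect_error(genotype_matrix(matrix(3L, 2, 1),
                               individual_ids = c("a", "b"),
                               population_of = pm),
               "not in \\{0, 1, 2, NA\\}")
  expect_error(genotype_matrix(matrix(0L, 2, 2),
                               individual_ids = c("a", "a"),
                               population_of = pm),
               "duplicate individual")
  expect_error(genotype_matrix(matrix(0L, 2, 2),
                               individual_ids = c("a", "z"),
                               population_of = pm),
               "absent from population map")
  expect_error(genotype_matrix(matrix(0L, 1, 2),
                               individual_ids = "a", population_of = pm),
               "at least 2 individuals")
})

test_that("TSV loader parses genotypes and flags one NA cell as missing", {
  dir <- withr::local_tempdir()
  geno <- file.path(dir, "g.tsv"); pmap <- file.path(dir, "pm.tsv")
  writeLines(c("locus_id\tA\tB\tC",
               "L1\t0\t1\t2",
               "L2\t2\tNA\t0"), geno)
  writeLines(c("individual_id\tpopulation",
               "A\tp1", "B\tp1", "C\tp2"), pmap)
  G <- load_genotype_matrix(geno, "tsv", pmap)
  expect_identical(dim(G$values), c(3L, 2L))
  expect_identical(sum(G$missing), 1L)
  expect_true(G$missing["B", "L2"])
  expect_identical(unname(G$values["C", ]), c(2L, 0L))

  writeLines(c("locus_id\tA\tB\tC", "L1\t0\tx\t2"), geno)
  expect_error(load_genotype_matrix(geno, "tsv", pmap),
               "unparseable genotype token 'x'")
})

test_that("VCF loader converts diploid GT and rejects triallelic records", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "g.vcf"); pmap <- file.path(dir, "pm.tsv")
  writeLines(c("individual_id\tpopulation",
               "S1\tp1", "S2\tp1", "S3\tp2"), pmap)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3")
  writeLines(c(hdr,
               "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
               "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t./.\t0|0\t1/0"), vcf)
  G <- load_genotype_matrix(vcf, "vcf", pmap)
  expect_identical(unname(G$values[, "rs1"]), c(0L, 1L, 2L))
  expect_true(G$missing["S1", "rs2"])
  expect_identical(unname(G$values["S3", "rs2"]), 1L)

  writeLines(c(hdr,
               "1\t100\trs1\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1"), vcf)
  expect_error(load_genotype_matrix(vcf, "vcf", pmap),
               "non-biallelic record at locus 'rs1'")
})

test_that("write/load TSV round-trip preserves values and missing mask", {
  sim <- simulate_lattice_dataset(
    sim_config(lattice_grid(2, 1), n_per_pop = 5, L = 50,
               spatial_sd = 0.5, missing_rate = 0.1, seed = 21))
  dir <- withr::local_tempdir()
  geno <- file.path(dir, "g.tsv"); pmap <- file.path(dir, "pm.tsv")
  write_genotype_tsv(sim$genotypes, geno, pmap)
  G2 <- load_genotype_matrix(geno, "tsv", pmap)
  expect_identical(G2$values, sim$genotypes$values)
  expect_identical(G2$missing, sim$genotypes$missing)
  expect_identical(G2$population_of, sim$genotypes$population_of)
})

test_that("missing-data filter removes strictly above the threshold only", {
  # 100 loci: individual b misses 6% (removed), c exactly 5% (retained)
  vals <- matrix(1L, 4, 100L)
  vals[2, 1:6] <- NA    # 6%
  vals[3, 1:5] <- NA    # exactly 5%
  ids <- letters[1:4]
  G <- genotype_matrix(vals, individual_ids = ids,
                       population_of = setNames(rep("p", 4), ids))
  res <- filter_missing_individuals(G, 0.05)
  expect_identical(res$removed, "b")
  expect_identical(res$genotypes$individual_ids, c("a", "c", "d"))

  # fully observed: identity, empty removal list
  G2 <- genotype_matrix(matrix(1L, 3, 4), individual_ids = letters[1:3],
                        population_of = setNames(rep("p", 3), letters[1:3]))
  res2 <- filter_missing_individuals(G2)
  expect_identical(res2$genotypes$values, G2$values)
  expect_length(res2$removed, 0L)

  expect_error(filter_missing_individuals(G, -0.1), "max_missing_fraction")
})

test_that("locus subsampling is deterministic, identity at L_sub = L, and uniform", {
  sim <- simulate_lattice_dataset(
    sim_config(lattice_grid(2, 1), n_per_pop = 4, L = 4,
               spatial_sd = 0.3, seed = 9))
  G <- sim$genotypes

  expect_identical(subsample_loci(G, 4, seed = 1)$values, G$values)

  s1 <- subsample_loci(G, 1, seed = 77)
  s2 <- subsample_loci(G, 1, seed = 77)
  expect_identical(s1$locus_ids, s2$locus_ids)
  expect_identical(s1$values, s2$values)

  expect_error(subsample_loci(G, 0, seed = 1), "L_sub")
  expect_error(subsample_loci(G, 5, seed = 1), "L_sub")

  # uniformity: 2000 draws of 2 loci from 4; each locus expected with
  # frequency 1/2, tolerance 3 binomial SEs
  draws <- 2000L
  counts <- table(unlist(lapply(seq_len(draws), function(s)
    subsample_loci(G, 2, seed = s)$locus_ids)))
  se <- sqrt(0.5 * 0.5 / draws)
  expect_true(all(abs(counts / draws - 0.5) < 3 * se))
})

test_that("locus subsampling reuses the same marker set across datasets sharing loci", {
  cfg <- sim_config(lattice_grid(3, 1), n_per_pop = 4, L = 200,
                    spatial_sd = 0.5, seed = 15)
  sim <- simulate_lattice_dataset(cfg)
  G_all <- sim$genotypes
  G_sub <- subset_individuals(G_all, G_all$population_of != "pop_3_1")
  expect_identical(subsample_loci(G_all, 50, seed = 4)$locus_ids,
                   subsample_loci(G_sub, 50, seed = 4)$locus_ids)
})
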