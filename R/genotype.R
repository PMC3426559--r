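#' Construct a validated genotype matrix
#'
#' The central data container of the package: a diploid SNP genotype matrix of
#' reference-allele counts (individuals in rows, loci in columns), together
#' with a missingness mask and a population assignment for every individual.
#'
#' @param values Integer matrix, n individuals x L loci, entries in
#'   \{0, 1, 2\} or `NA` for missing genotypes.
#' @param individual_ids Character vector of n unique individual identifiers.
#'   Defaults to the rownames of `values`.
#' @param population_of Named character vector mapping every individual id to
#'   a population label.
#' @param locus_ids Character vector of L unique locus identifiers. Defaults
#'   to the colnames of `values`.
#'
#' @return An object of class `genotype_matrix` with elements `values`
#'   (integer matrix with `NA` at missing genotypes), `missing` (logical
#'   mask), `individual_ids`, `population_of` (named vector aligned with
#'   individuals), and `locus_ids`.
#' @export
genotype_matrix <- function(values, individual_ids = rownames(values),
                            population_of, locus_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(individual_ids))
    individual_ids <- paste0("ind", seq_len(nrow(values)))
  if (is.null(locus_ids))
    locus_ids <- paste0("locus", seq_len(ncol(values)))
  individual_ids <- as.character(individual_ids)
  locus_ids <- as.character(locus_ids)

  n <- nrow(values); L <- ncol(values)
  if (n < 2L) stop("genotype matrix needs at least 2 individuals")
  if (L < 1L) stop("genotype matrix needs at least 1 locus")
  if (length(individual_ids) != n) stop("individual_ids length != nrow(values)")
  if (length(locus_ids) != L) stop("locus_ids length != ncol(values)")
  if (anyDuplicated(individual_ids))
    stop("duplicate individual ids: ",
         paste(unique(individual_ids[duplicated(individual_ids)]), collapse = ", "))
  if (anyDuplicated(locus_ids))
    stop("duplicate locus ids: ",
         paste(unique(locus_ids[duplicated(locus_ids)]), collapse = ", "))

  storage.mode(values) <- "integer"
  bad <- !is.na(values) & !(values %in% 0:2)
  if (any(bad)) {
    j <- which(bad, arr.ind = TRUE)[1L, ]
    stop("genotype at individual '", individual_ids[j[1L]], "', locus '",
         locus_ids[j[2L]], "' is not in {0, 1, 2, NA}")
  }

  missing_in_map <- setdiff(individual_ids, names(population_of))
  if (length(missing_in_map))
    stop("individuals absent from population map: ",
         paste(missing_in_map, collapse = ", "))
  pops <- as.character(population_of[individual_ids])
  names(pops) <- individual_ids
  if (anyNA(pops)) stop("population labels contain NA")

  dimnames(values) <- list(individual_ids, locus_ids)
  structure(
    list(values = values,
         missing = is.na(values),
         individual_ids = individual_ids,
         population_of = pops,
         locus_ids = locus_ids),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x$values), " individuals x ",
      ncol(x$values), " loci, ",
      length(unique(x$population_of)), " populations, ",
      sprintf("%.2f%%", 100 * mean(x$missing)), " missing\n", sep = "")
  invisible(x)
}

#' Number of individuals / loci in a genotype matrix
#' @param G A `genotype_matrix`.
#' @return Integer count.
#' @export
n_individuals <- function(G) nrow(G$values)

#' @rdname n_individuals
#' @export
n_loci <- function(G) ncol(G$values)

#' Restrict a genotype matrix to a subset of individuals
#'
#' Pure row deletion: retained genotype values and their ordering are
#' untouched.
#'
#' @param G A `genotype_matrix`.
#' @param keep Character vector of individual ids, or logical/integer index.
#' @return A `genotype_matrix` with the selected individuals.
#' @export
subset_individuals <- function(G, keep) {
  if (is.character(keep)) keep <- match(keep, G$individual_ids)
  ids <- G$individual_ids[keep]
  genotype_matrix(G$values[keep, , drop = FALSE],
                  individual_ids = ids,
                  population_of = G$population_of[ids],
                  locus_ids = G$locus_ids)
}

read_popmap <- function(popmap_path) {
  if (!file.exists(popmap_path)) stop("population map not found: ", popmap_path)
  pm <- utils::read.delim(popmap_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("individual_id", "population")
  if (!all(need %in% names(pm)))
    stop("population map must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(pm$individual_id))
    stop("duplicate individual ids in population map")
  stats::setNames(as.character(pm$population), pm$individual_id)
}

#' Load a genotype matrix from a TSV or VCF file
#'
#' Two dialects are supported. `format = "tsv"` reads a transposed-raw-style
#' table: a header row of individual ids preceded by a `locus_id` column, one
#' row per locus, cells in \{0, 1, 2\} with `NA` as the missing code. `format
#' = "vcf"` reads a VCF v4.x and converts diploid `GT` fields to alternate
#' allele counts (`./.` becomes missing); records that are not biallelic SNP
#' genotypes raise an error naming the locus.
#'
#' @param path Path to the genotype file.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @param popmap_path Path to a tab-delimited population map with columns
#'   `individual_id` and `population`; every sample in the genotype file must
#'   appear in it.
#' @return A validated [genotype_matrix()].
#' @export
load_genotype_matrix <- function(path, format = c("tsv", "vcf"), popmap_path) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  popmap <- read_popmap(popmap_path)

  if (format == "tsv") {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    if (!"locus_id" %in% names(tab))
      stop("genotype TSV must have a 'locus_id' column")
    locus_ids <- as.character(tab$locus_id)
    ind_ids <- setdiff(names(tab), "locus_id")
    cells <- as.matrix(tab[, ind_ids, drop = FALSE])
    ok <- is.na(cells) | cells %in% c("0", "1", "2", "NA")
    if (!all(ok)) {
      j <- which(!ok, arr.ind = TRUE)[1L, ]
      stop("unparseable genotype token '", cells[j[1L], j[2L]],
           "' at locus '", locus_ids[j[1L]], "', individual '",
           ind_ids[j[2L]], "'")
    }
    vals <- suppressWarnings(matrix(as.integer(cells), nrow = nrow(cells)))
    values <- t(vals)                       # individuals x loci
    genotype_matrix(values, individual_ids = ind_ids,
                    population_of = popmap, locus_ids = locus_ids)
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix)))                  # single-record files
      fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
    locus_ids <- fix[, "ID"]
    blank <- is.na(locus_ids) | locus_ids == "." | locus_ids == ""
    locus_ids[blank] <- paste0(fix[blank, "CHROM"], ":", fix[blank, "POS"])
    multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
    if (any(multi))
      stop("non-biallelic record at locus '", locus_ids[which(multi)[1L]], "'")
    gt <- vcfR::extract.gt(vcf, element = "GT")
    counts <- apply(gt, c(1, 2), function(g) {
      if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_integer_)
      alleles <- strsplit(g, "[/|]")[[1L]]
      if (length(alleles) != 2L || !all(alleles %in% c("0", "1")))
        return(-1L)
      sum(alleles == "1")
    })
    if (any(counts == -1L, na.rm = TRUE)) {
      j <- which(counts == -1L, arr.ind = TRUE)[1L, ]
      stop("non-diploid or non-biallelic genotype at locus '",
           locus_ids[j[1L]], "'")
    }
    genotype_matrix(t(counts), individual_ids = colnames(gt),
                    population_of = popmap, locus_ids = locus_ids)
  }
}

#' Write a genotype matrix and its population map as TSV
#'
#' Emits the canonical tab-delimited dialect read back by
#' [load_genotype_matrix()]: loci in rows, individuals in columns, `NA` as
#' the missing code.
#'
#' @param G A `genotype_matrix`.
#' @param path Output path for the genotype table.
#' @param popmap_path Optional output path for the population map TSV.
#' @return Invisibly, `path`.
#' @export
write_genotype_tsv <- function(G, path, popmap_path = NULL) {
  tab <- data.frame(locus_id = G$locus_ids,
                    t(G$values), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(popmap_path)) {
    pm <- data.frame(individual_id = G$individual_ids,
                     population = unname(G$population_of),
                     stringsAsFactors = FALSE)
    utils::write.table(pm, popmap_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Subsample loci uniformly at random
#'
#' Draws `L_sub` distinct loci without replacement. The same
#' `(seed, L_sub)` pair always selects the same loci, and because selection
#' is by column index over a shared locus list, datasets sharing
#' `locus_ids` receive the same marker set — so results for different
#' regions are comparable marker-for-marker.
#'
#' @param G A `genotype_matrix`.
#' @param L_sub Number of loci to keep, between 1 and `n_loci(G)`.
#' @param seed Integer seed controlling the draw.
#' @return A `genotype_matrix` restricted to the sampled loci (original
#'   column order preserved).
#' @export
subsample_loci <- function(G, L_sub, seed) {
  L <- n_loci(G)
  if (L_sub < 1L || L_sub > L)
    stop("L_sub must be between 1 and ", L)
  idx <- with_seed(seed, sort(sample.int(L, L_sub)))
  genotype_matrix(G$values[, idx, drop = FALSE],
                  individual_ids = G$individual_ids,
                  population_of = G$population_of,
                  locus_ids = G$locus_ids[idx])
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
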