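# Independent oracles and fixture builders shared across the test files.

# Brute-force Procrustes similarity: sweep the rotation angle on a dense
# grid (with and without a reflection factor), using the closed-form optimal
# scale/translation at each angle, then refine the best angle numerically.
# Deliberately avoids the SVD route used by the implementation.
brute_force_t0 <- function(X, Y, allow_reflection = TRUE, grid_n = 2000L) {
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  trX <- sum(Xc^2); trY <- sum(Yc^2)
  C <- crossprod(Yc, Xc)                    # Y_c^T X_c
  val <- function(theta, refl) {
    R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
    A <- if (refl) diag(c(1, -1)) %*% R else R
    sum(A * C)                              # trace(A^T C)
  }
  best <- 0
  for (refl in if (allow_reflection) c(FALSE, TRUE) else FALSE) {
    thetas <- seq(0, 2 * pi, length.out = grid_n + 1L)[-(grid_n + 1L)]
    vals <- vapply(thetas, val, numeric(1), refl = refl)
    i <- which.max(vals)
    lo <- thetas[i] - 2 * pi / grid_n
    hi <- thetas[i] + 2 * pi / grid_n
    opt <- stats::optimize(val, c(lo, hi), refl = refl, maximum = TRUE,
                           tol = 1e-12)
    best <- max(best, opt$objective, vals[i])
  }
  max(best, 0) / sqrt(trX * trY)
}

# Literal per-locus transcription of the Weir-Cockerham variance components
# (scalar loop, no vectorization) as an independent check of the
# implementation's ratio-of-sums estimate.
wc_theta_oracle <- function(G) {
  pop <- G$population_of
  pops <- unique(pop)
  A <- B <- Cc <- 0
  for (l in seq_len(n_loci(G))) {
    g <- G$values[, l]
    ns <- ps <- hs <- numeric(0)
    for (pp in pops) {
      gi <- g[pop == pp]
      gi <- gi[!is.na(gi)]
      if (length(gi) == 0L) next
      ns <- c(ns, length(gi))
      ps <- c(ps, sum(gi) / (2 * length(gi)))
      hs <- c(hs, mean(gi == 1L))
    }
    r <- length(ns)
    if (r < 2L) next
    nbar <- mean(ns)
    if (nbar <= 1) next
    nsum <- sum(ns)
    pbar <- sum(ns * ps) / nsum
    if (pbar <= 0 || pbar >= 1) next
    hbar <- sum(ns * hs) / nsum
    s2 <- sum(ns * (ps - pbar)^2) / ((r - 1) * nbar)
    nc <- (nsum - sum(ns^2) / nsum) / (r - 1)
    if (nc <= 0) next
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; Cc <- Cc + cc
  }
  A / (A + B + Cc)
}

# Random 2-D point configuration.
random_config <- function(n, scale = 1) {
  matrix(stats::rnorm(2 * n, sd = scale), n, 2)
}

# Apply a random similarity transform (optionally with reflection) to a
# configuration of row-vector points.
random_similarity <- function(P, reflect = FALSE) {
  th <- stats::runif(1, 0, 2 * pi)
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  if (reflect) R <- diag(c(1, -1)) %*% R
  s <- stats::runif(1, 0.2, 5)
  b <- stats::rnorm(2, sd = 10)
  s * (P %*% R) + rep(b, each = nrow(P))
}

# Homogeneous cohort (one panmictic population) with optional planted
# outliers. Outlier A's genotype frequencies are pushed to near-fixation
# opposite the cohort; outlier B (cascade = TRUE) sits at `w_b` of the way
# from the cohort frequencies toward A's, collinear with A by construction.
make_outlier_cohort <- function(n0, L, seed, plant = c("none", "single",
                                                       "cascade"),
                                single_shift = 0.45, w_b = 0.5) {
  plant <- match.arg(plant)
  set.seed(seed)
  p <- stats::runif(L, 0.2, 0.8)
  vals <- matrix(stats::rbinom(n0 * L, 2, rep(p, each = n0)), n0, L)
  ids <- paste0("i", seq_len(n0))
  if (plant == "single") {
    q <- ifelse(p < 0.5, p + single_shift, p - single_shift)
    vals <- rbind(vals, stats::rbinom(L, 2, q))
    ids <- c(ids, "outA")
  } else if (plant == "cascade") {
    qA <- ifelse(p < 0.5, 0.98, 0.02)
    qB <- p + w_b * (qA - p)
    vals <- rbind(vals, stats::rbinom(L, 2, qA), stats::rbinom(L, 2, qB))
    ids <- c(ids, "outA", "outB")
  }
  genotype_matrix(vals, individual_ids = ids,
                  population_of = stats::setNames(rep("pop1", nrow(vals)),
                                                  ids))
}

# Small irregular (asymmetric) population layout; irregularity avoids the
# t0 ties that symmetric lattices create among permuted assignments.
irregular_grid <- function(K, seed, span = 40) {
  set.seed(seed)
  data.frame(population = paste0("p", seq_len(K)),
             longitude = stats::runif(K, 0, span),
             latitude = stats::runif(K, 0, span),
             stringsAsFactors = FALSE)
}
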