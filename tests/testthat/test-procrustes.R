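test_that("identity and pure-rotation inputs are fit exactly", {
  set.seed(1)
  X <- random_config(10)
  f <- procrustes_fit(X, X)
  expect_equal(f$t0, 1, tolerance = 1e-12)
  expect_equal(f$D, 0, tolerance = 1e-12)
  expect_equal(f$rotation_deg, 0, tolerance = 1e-9)
  expect_false(f$reflection_used)
  expect_equal(f$scale, 1, tolerance = 1e-12)

  # moving set = X rotated +90 degrees about its centroid: the fit
  # un-rotates by -90
  th <- pi / 2
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  ctr <- colMeans(X)
  Y <- sweep(sweep(X, 2, ctr) %*% R, 2, ctr, "+")
  f2 <- procrustes_fit(X, Y)
  expect_equal(f2$t0, 1, tolerance = 1e-12)
  expect_equal(f2$rotation_deg, -90, tolerance = 1e-9)
  expect_equal(f2$transformed, X, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("reflected targets need the reflection family", {
  set.seed(2)
  X <- random_config(8)
  Y <- X %*% diag(c(-1, 1))          # mirror across the vertical axis
  f_free <- procrustes_fit(X, Y, allow_reflection = TRUE)
  expect_equal(f_free$t0, 1, tolerance = 1e-12)
  expect_true(f_free$reflection_used)
  f_rot <- procrustes_fit(X, Y, allow_reflection = FALSE)
  expect_lt(f_rot$t0, 1 - 1e-6)
  expect_false(f_rot$reflection_used)
})

test_that("closed-form t0 matches the brute-force oracle", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    X <- random_config(n, scale = runif(1, 0.5, 3))
    Y <- random_config(n, scale = runif(1, 0.5, 3))
    for (ar in c(TRUE, FALSE)) {
      expect_equal(procrustes_t0(X, Y, allow_reflection = ar),
                   brute_force_t0(X, Y, allow_reflection = ar),
                   tolerance = 1e-6)
    }
  }
})

test_that("t0 agrees with vegan's symmetric Procrustes correlation", {
  skip_if_not_installed("vegan")
  set.seed(12)
  for (i in 1:5) {
    X <- random_config(12); Y <- random_config(12)
    ss <- vegan::procrustes(X, Y, symmetric = TRUE)$ss
    expect_equal(procrustes_t0(X, Y), sqrt(1 - ss), tolerance = 1e-9)
  }
})

test_that("t0 is bounded, similarity-invariant, and 1 iff similarity-related", {
  set.seed(3)
  for (i in 1:25) {
    n <- sample(3:20, 1)
    X <- random_config(n); Y <- random_config(n)
    t0 <- procrustes_t0(X, Y)
    expect_gte(t0, 0); expect_lte(t0, 1)
    # invariance under separate similarity transforms of either input
    expect_equal(procrustes_t0(random_similarity(X), Y), t0,
                 tolerance = 1e-9)
    expect_equal(procrustes_t0(X, random_similarity(Y, reflect = TRUE)),
                 t0, tolerance = 1e-9)
    # similarity-related pairs reach exactly 1; generic pairs do not
    expect_equal(procrustes_t0(X, random_similarity(X, reflect = i %% 2 == 0)),
                 1, tolerance = 1e-9)
    if (n > 3) expect_lt(t0, 1 - 1e-9)
  }
})

test_that("residual scaling ties D to the target dispersion", {
  set.seed(5)
  X <- random_config(9); Y <- random_config(9)
  f <- procrustes_fit(X, Y)
  Xc <- sweep(X, 2, colMeans(X))
  ss_resid <- sum((f$transformed - X)^2)
  expect_equal(ss_resid, f$D * sum(Xc^2), tolerance = 1e-9)
  expect_equal(f$t0, sqrt(1 - f$D), tolerance = 1e-12)
})

test_that("D decreases as the moving set is interpolated toward a match", {
  set.seed(6)
  X <- random_config(10); Y <- random_config(10)
  target <- random_similarity(X)           # a perfect-match configuration
  alphas <- seq(0, 1, by = 0.25)
  Ds <- vapply(alphas, function(a)
    procrustes_fit(X, (1 - a) * Y + a * target)$D, numeric(1))
  expect_true(all(diff(Ds) < 1e-12))
  expect_equal(Ds[length(Ds)], 0, tolerance = 1e-12)
})

test_that("shape is preserved: transformed pairwise distances scale uniformly", {
  set.seed(8)
  X <- random_config(7); Y <- random_config(7)
  f <- procrustes_fit(X, Y)
  d_in <- as.numeric(dist(Y)); d_out <- as.numeric(dist(f$transformed))
  expect_equal(d_out, f$scale * d_in, tolerance = 1e-9)
})

test_that("superimpose applies the stored transformation exactly", {
  set.seed(9)
  X <- random_config(6); Y <- random_config(6)
  for (ar in c(TRUE, FALSE)) {
    f <- procrustes_fit(X, Y %*% diag(c(-1, 1)), allow_reflection = ar)
    Ym <- Y %*% diag(c(-1, 1))
    expect_equal(superimpose(f, Ym), f$transformed, tolerance = 1e-12)
    # centroid maps to centroid (affine property)
    expect_equal(as.numeric(superimpose(f, t(colMeans(Ym)))),
                 colMeans(f$transformed), tolerance = 1e-9)
    # angles preserved: orthogonal unit directions stay orthogonal
    ctr <- colMeans(Ym)
    pts <- rbind(ctr, ctr + c(1, 0), ctr + c(0, 1))
    img <- superimpose(f, pts)
    v1 <- img[2, ] - img[1, ]; v2 <- img[3, ] - img[1, ]
    expect_equal(sum(v1 * v2), 0, tolerance = 1e-9)
  }
})

test_that("degenerate inputs are rejected", {
  X <- random_config(5)
  expect_error(procrustes_fit(X[1:2, ], X[1:2, ]), "at least 3")
  expect_error(procrustes_fit(matrix(1, 5, 2), X), "zero dispersion")
  expect_error(procrustes_fit(X, matrix(2, 5, 2)), "zero dispersion")
})
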