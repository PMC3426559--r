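#' Procrustes superposition of one 2-D map onto another
#'
#' Finds, among all combinations of translation, scaling, rotation and
#' (optionally) reflection of the moving configuration, the transformation
#' minimizing the sum of squared Euclidean distances to the fixed target
#' configuration. Relative pairwise distances within the moving set are
#' preserved up to the single global scale. The minimized sum of squares,
#' scaled by the target's total dispersion, gives `D` in \[0, 1\] and the
#' similarity statistic `t0 = sqrt(1 - D)`. In the genes-vs-geography
#' pipeline the geographic coordinates are the fixed target and the PC1-PC2
#' map is transformed.
#'
#' Closed form: with both sets centered, let the 2 x 2 cross-product matrix
#' have singular values \eqn{\sigma_1 \ge \sigma_2}; then
#' \eqn{t_0 = (\sigma_1 + \sigma_2) / \sqrt{\mathrm{tr}(X_c^T X_c)\,
#' \mathrm{tr}(Y_c^T Y_c)}}. When reflection is disallowed and the
#' unconstrained optimum has negative determinant, \eqn{\sigma_2} enters
#' with a minus sign instead.
#'
#' @param X_target n x 2 matrix, the fixed configuration.
#' @param Y_moving n x 2 matrix, the configuration to be transformed;
#'   row i corresponds to row i of `X_target`.
#' @param allow_reflection Include reflections in the transformation family
#'   (default TRUE).
#' @return An object of class `procrustes_fit`: `t0`, `D`, `rotation_deg`
#'   (degrees counterclockwise in (-180, 180\]; when `reflection_used`, the
#'   angle of the rotation factor after writing the orthogonal part as
#'   reflection-across-the-x-axis followed by rotation), `reflection_used`,
#'   `scale`, `translation` (length-2), and `transformed` (the moved
#'   configuration).
#' @export
procrustes_fit <- function(X_target, Y_moving, allow_reflection = TRUE) {
  X <- as.matrix(X_target); Y <- as.matrix(Y_moving)
  if (ncol(X) != 2L || ncol(Y) != 2L) stop("configurations must be n x 2")
  n <- nrow(X)
  if (nrow(Y) != n) stop("configurations must have the same number of rows")
  if (n < 3L) stop("Procrustes fit needs at least 3 points")

  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  trX <- sum(Xc^2); trY <- sum(Yc^2)
  if (trX <= 0) stop("target configuration has zero dispersion")
  if (trY <= 0) stop("moving configuration has zero dispersion")

  sv <- svd(crossprod(Yc, Xc))             # Y_c^T X_c = U diag(sigma) V^T
  refl <- det(sv$u %*% t(sv$v)) < 0
  if (refl && !allow_reflection) {
    A <- sv$u %*% diag(c(1, -1)) %*% t(sv$v)
    trace_val <- sv$d[1L] - sv$d[2L]
    reflection_used <- FALSE
  } else {
    A <- sv$u %*% t(sv$v)
    trace_val <- sum(sv$d)
    reflection_used <- refl
  }

  s <- max(trace_val, 0) / trY
  t0 <- max(trace_val, 0) / sqrt(trX * trY)
  t0 <- min(t0, 1)
  D <- 1 - t0^2
  translation <- as.numeric(mx - s * (my %*% A))
  transformed <- s * (Y %*% A) + rep(translation, each = n)

  # rotation angle of the orthogonal factor, for row-vector action y %*% A;
  # under reflection, factor A = reflect(x-axis) %*% R and report R's angle
  R <- if (det(A) < 0) diag(c(1, -1)) %*% A else A
  rotation_deg <- atan2(R[1L, 2L], R[1L, 1L]) * 180 / pi

  structure(
    list(t0 = t0, D = D,
         rotation_deg = rotation_deg,
         reflection_used = reflection_used,
         scale = s, translation = translation,
         orthogonal = A,
         transformed = transformed),
    class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat(sprintf(
    "procrustes_fit: t0 = %.4f, D = %.4f, rotation = %.2f deg CCW%s\n",
    x$t0, x$D, x$rotation_deg,
    if (x$reflection_used) " (reflected)" else ""))
  invisible(x)
}

#' Apply a stored Procrustes transformation to additional points
#'
#' Applies exactly the fitted translation, scale and orthogonal map to
#' auxiliary points expressed in the moving configuration's coordinate
#' system — e.g. PC-axis endpoints for drawing superimposed axes.
#'
#' @param fit A `procrustes_fit`.
#' @param extra_points m x 2 matrix.
#' @return m x 2 matrix of transformed points.
#' @export
superimpose <- function(fit, extra_points) {
  P <- as.matrix(extra_points)
  if (ncol(P) != 2L) stop("extra_points must be m x 2")
  fit$scale * (P %*% fit$orthogonal) + rep(fit$translation, each = nrow(P))
}

# Fast path used inside permutation loops: t0 only, given a pre-centered
# moving configuration Yc with dispersion trY.
t0_stat <- function(Xc, trX, Yc, trY, allow_reflection = TRUE) {
  sv <- svd(crossprod(Yc, Xc))
  tv <- if (!allow_reflection && det(sv$u %*% t(sv$v)) < 0)
    sv$d[1L] - sv$d[2L] else sum(sv$d)
  min(max(tv, 0) / sqrt(trX * trY), 1)
}

#' Procrustes similarity between two configurations
#'
#' Convenience wrapper returning only `t0`.
#'
#' @inheritParams procrustes_fit
#' @return The similarity statistic t0 in \[0, 1\].
#' @export
procrustes_t0 <- function(X_target, Y_moving, allow_reflection = TRUE) {
  procrustes_fit(X_target, Y_moving, allow_reflection)$t0
}
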