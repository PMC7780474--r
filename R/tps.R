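#' Fit a 3D thin-plate spline between two point sets
#'
#' Solves the bordered TPS system with radial kernel `U(r) = |r|` (sign fixed
#' so the bending-energy quadratic form is positive semidefinite in 3D). With
#' `lambda = 0` the warp interpolates every target exactly; `lambda > 0`
#' gives a smoothing fit for near-duplicate landmark rescue. When the source
#' is coplanar or has fewer than 5 points, an affine-only least-squares map is
#' fitted instead (zero non-affine part).
#'
#' @param source,target numeric k x 3 matrices in row correspondence.
#' @param lambda numeric >= 0 regularization.
#' @return A [TPSModel-class].
#' @examples
#' src <- matrix(rnorm(30), 10, 3)
#' m <- fitTPS(src, 2 * src + 1)
#' max(abs(warpPoints(m, src) - (2 * src + 1)))
#' @seealso [warpPoints()], [bendingEnergy()]
#' @export
fitTPS <- function(source, target, lambda = 0) {
  source <- as.matrix(source)
  target <- as.matrix(target)
  stopifnot(nrow(source) == nrow(target), ncol(source) == 3L, ncol(target) == 3L)
  if (lambda < 0) stop("lambda must be >= 0")
  k <- nrow(source)
  # same distance evaluation as warpPoints(), so the fitted system is
  # reproduced exactly when probing at the source points
  r <- .crossDist(source, source)
  diag(r) <- 0
  if (lambda == 0 && k > 1L && min(r[upper.tri(r)]) == 0) {
    stop("duplicate source points with lambda = 0; jitter them or use lambda > 0")
  }
  P <- cbind(1, source)
  degenerate <- k < 5L || qr(sweep(source, 2L, colMeans(source)))$rank < 3L
  if (degenerate) {
    # minimal-norm least squares; P is rank-deficient for coplanar sources
    sv <- svd(P)
    pos <- sv$d > max(sv$d) * 1e-10
    affine <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% target) / sv$d[pos])
    return(new("TPSModel",
      sourcePoints = source, targetPoints = target,
      nonaffineWeights = matrix(0, k, 3L), affine = affine,
      kernelMatrix = -r, bendingEnergyMatrix = matrix(0, k, k),
      lambda = lambda
    ))
  }
  K <- -r
  L <- rbind(
    cbind(K + diag(lambda, k), P),
    cbind(t(P), matrix(0, 4L, 4L))
  )
  cond <- kappa(L, exact = FALSE)
  if (is.finite(cond) && cond > 1e12) {
    warning(sprintf("TPS system is ill-conditioned (kappa ~ %.3g)", cond))
  }
  Li <- solve(L)
  rhs <- rbind(target, matrix(0, 4L, 3L))
  sol <- Li %*% rhs
  # two steps of iterative refinement keep node residuals near machine
  # precision even for poorly scaled source configurations
  for (it in 1:2) sol <- sol + Li %*% (rhs - L %*% sol)
  B <- Li[seq_len(k), seq_len(k), drop = FALSE]
  B <- (B + t(B)) / 2
  new("TPSModel",
    sourcePoints = source, targetPoints = target,
    nonaffineWeights = sol[seq_len(k), , drop = FALSE],
    affine = sol[k + 1:4, , drop = FALSE],
    kernelMatrix = K, bendingEnergyMatrix = B,
    lambda = lambda
  )
}

#' Warp points through a fitted thin-plate spline
#'
#' Applies the continuous TPS interpolant to arbitrary probes; applied to a
#' template mesh's vertices this produces the warped intermediate model used
#' by the patching step.
#'
#' @param model a [TPSModel-class].
#' @param probes numeric m x 3 matrix (or 3-vector).
#' @return numeric m x 3 matrix of warped coordinates.
#' @export
warpPoints <- function(model, probes) {
  p <- if (is.null(dim(probes))) matrix(probes, 1L, 3L) else as.matrix(probes)
  U <- -.crossDist(p, model@sourcePoints)
  cbind(1, p) %*% model@affine + U %*% model@nonaffineWeights
}

#' Warp a mesh through a fitted thin-plate spline
#'
#' @param model a [TPSModel-class].
#' @param mesh a [TriMesh-class]; its vertices are warped, faces kept, and
#'   vertex normals recomputed.
#' @return The warped [TriMesh-class].
#' @export
warpMesh <- function(model, mesh) {
  TriMesh(warpPoints(model, mesh@vertices), mesh@faces,
    dialect = mesh@dialect, fixWinding = FALSE
  )
}

#' Bending energy of a thin-plate spline deformation
#'
#' The quadratic deformation measure minimized when semilandmarks slide:
#' `trace(t(T) %*% B %*% T)` where `B` is the bending-energy matrix of the
#' source configuration and `T` the target coordinates. Zero exactly when the
#' target is an affine image of the source; invariant to simultaneous rigid
#' motion of both configurations.
#'
#' @param source,target numeric k x 3 matrices, or a fitted [TPSModel-class]
#'   as `source` (then `target` defaults to its stored target).
#' @return numeric scalar >= 0.
#' @export
bendingEnergy <- function(source, target = NULL) {
  if (is(source, "TPSModel")) {
    model <- source
    if (is.null(target)) target <- model@targetPoints
  } else {
    model <- fitTPS(source, target)
  }
  e <- sum(diag(t(target) %*% model@bendingEnergyMatrix %*% as.matrix(target)))
  max(e, 0)
}

#' Bending-energy matrix of a source configuration
#'
#' Symmetric positive semidefinite k x k matrix of rank at most k - 4 that
#' annihilates affine configurations.
#'
#' @param source numeric k x 3 matrix.
#' @param lambda numeric >= 0.
#' @return numeric k x k matrix.
#' @export
bendingEnergyMatrix <- function(source, lambda = 0) {
  fitTPS(source, as.matrix(source), lambda = lambda)@bendingEnergyMatrix
}

# Euclidean distances between the rows of two matrices. Computed from
# coordinate differences (not the expanded a^2 + b^2 - 2ab form) so small
# distances keep full relative accuracy; probes coinciding with kernel
# centers must evaluate to exactly zero.
.crossDist <- function(a, b) {
  sqrt(
    outer(a[, 1L], b[, 1L], "-")^2 +
      outer(a[, 2L], b[, 2L], "-")^2 +
      outer(a[, 3L], b[, 3L], "-")^2
  )
}
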