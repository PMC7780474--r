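# Generalized Procrustes alignment, Procrustes distance, mean specimen, PCA.

# Optimal rotation (optionally allowing reflection) aligning B onto A,
# both already centered. Returns the rotation matrix R so that B %*% R ~ A.
.optimalRotation <- function(A, B, allowReflection = FALSE) {
  s <- svd(crossprod(B, A))
  R <- s$u %*% t(s$v)
  if (!allowReflection && det(R) < 0) {
    u <- s$u
    u[, 3L] <- -u[, 3L]
    R <- u %*% t(s$v)
  }
  R
}

.centerScale <- function(X) {
  X <- sweep(X, 2L, colMeans(X))
  X / sqrt(sum(X^2))
}

# Coerce a list of LandmarkConfig or a k x 3 x n array to an array + metadata.
.asShapeArray <- function(configs) {
  if (is.array(configs) && length(dim(configs)) == 3L) {
    ids <- dimnames(configs)[[3L]]
    if (is.null(ids)) ids <- sprintf("spec%03d", seq_len(dim(configs)[3L]))
    labels <- dimnames(configs)[[1L]]
    if (is.null(labels)) labels <- sprintf("p%03d", seq_len(dim(configs)[1L]))
    dimnames(configs) <- list(labels, c("x", "y", "z"), ids)
    return(list(arr = configs, points = NULL))
  }
  stopifnot(is.list(configs), length(configs) >= 1L)
  labels <- configs[[1L]]@points$label
  for (cfg in configs) {
    if (!identical(cfg@points$label, labels)) {
      stop("configurations do not share one canonical point order")
    }
  }
  ids <- vapply(configs, specimenId, "")
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  arr <- array(NA_real_, c(length(labels), 3L, length(configs)),
    dimnames = list(labels, c("x", "y", "z"), ids)
  )
  for (i in seq_along(configs)) arr[, , i] <- configs[[i]]@coords
  list(arr = arr, points = configs[[1L]]@points)
}

#' Generalized Procrustes analysis with PCA of aligned shapes
#'
#' Removes position (centering), scale (unit centroid size) and orientation
#' (iterative rotation to the evolving mean shape) from a sample of
#' configurations, then runs a principal component analysis of the aligned
#' coordinates about the mean (covariance scaled by `1/(n-1)`). The summed
#' squared distance to the mean is non-increasing over iterations; the trace
#' is attached as attribute `"objectiveTrace"`.
#'
#' @param configs list of [LandmarkConfig-class] (shared point order) or a
#'   k x 3 x n array.
#' @param allow_reflection logical; allow improper rotations (default `FALSE`
#'   because anatomical shapes are chiral).
#' @param tol convergence tolerance on the change of the mean shape.
#' @param max_iterations iteration cap.
#' @return An [AlignmentResult-class].
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' arr <- array(c(a, a * 2 + 5), c(10, 3, 2))
#' res <- gpa(arr)
#' procrustesDistance(alignedArray(res)[, , 1], alignedArray(res)[, , 2])
#' @export
gpa <- function(configs, allow_reflection = FALSE, tol = 1e-10,
                max_iterations = 200L) {
  parsed <- .asShapeArray(configs)
  arr <- parsed$arr
  k <- dim(arr)[1L]
  n <- dim(arr)[3L]
  if (n < 2L) stop("need at least 2 configurations")
  if (k < 3L) stop("need at least 3 points")
  sizes <- apply(arr, 3L, centroidSize)
  names(sizes) <- dimnames(arr)[[3L]]
  aligned <- arr
  for (i in seq_len(n)) aligned[, , i] <- .centerScale(arr[, , i])
  ref <- aligned[, , 1L]
  objective <- numeric(0)
  for (iter in seq_len(max_iterations)) {
    for (i in seq_len(n)) {
      aligned[, , i] <- aligned[, , i] %*%
        .optimalRotation(ref, aligned[, , i], allow_reflection)
    }
    newmean <- apply(aligned, c(1L, 2L), mean)
    newmean <- newmean / sqrt(sum(newmean^2))
    objective <- c(objective, sum((sweep(aligned, c(1L, 2L), newmean))^2))
    if (sqrt(sum((newmean - ref)^2)) < tol && iter > 1L) {
      ref <- newmean
      break
    }
    ref <- newmean
  }
  flat <- t(apply(aligned, 3L, as.vector)) # n x 3k
  mu <- colMeans(flat)
  Xc <- sweep(flat, 2L, mu)
  sv <- svd(Xc)
  r <- sum(sv$d > max(sv$d) * 1e-12)
  values <- sv$d[seq_len(r)]^2 / (n - 1)
  scores <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r)
  rownames(scores) <- dimnames(arr)[[3L]]
  colnames(scores) <- sprintf("PC%d", seq_len(r))
  points <- parsed$points
  if (is.null(points)) {
    points <- data.frame(
      label = dimnames(arr)[[1L]], class = "landmark", region = "all",
      curve_id = NA_character_, ordinal = NA_integer_, side = "none",
      stringsAsFactors = FALSE
    )
  }
  res <- new("AlignmentResult",
    aligned = aligned, points = points, meanShape = ref,
    centroidSizes = sizes,
    pca = list(values = values, vectors = sv$v[, seq_len(r), drop = FALSE], scores = scores)
  )
  attr(res, "objectiveTrace") <- objective
  res
}

#' Procrustes distance between two configurations
#'
#' Root summed squared difference after removing translation, scale (both
#' shapes at unit centroid size) and rotation. Symmetric, and zero exactly
#' for similar shapes.
#'
#' @param a,b numeric k x 3 matrices or [LandmarkConfig-class] objects with
#'   equal point counts.
#' @param allow_reflection logical, as in [gpa()].
#' @return numeric scalar >= 0.
#' @export
procrustesDistance <- function(a, b, allow_reflection = FALSE) {
  A <- if (is(a, "LandmarkConfig")) a@coords else as.matrix(a)
  B <- if (is(b, "LandmarkConfig")) b@coords else as.matrix(b)
  if (!all(dim(A) == dim(B))) stop("configurations differ in size")
  A <- .centerScale(A)
  B <- .centerScale(B)
  B <- B %*% .optimalRotation(A, B, allow_reflection)
  sqrt(sum((A - B)^2))
}

#' Specimen closest to the mean shape
#'
#' Returns the specimen id minimizing the Procrustes distance to the sample
#' mean shape — the usual pick for a within-sample template mesh. Ties break
#' lexicographically by id.
#'
#' @param result an [AlignmentResult-class].
#' @return character specimen id.
#' @export
findMeanSpec <- function(result) {
  arr <- result@aligned
  ids <- dimnames(arr)[[3L]]
  d <- vapply(seq_along(ids), function(i) {
    procrustesDistance(result@meanShape, arr[, , i])
  }, 1)
  ids[order(d, ids)][1L]
}
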