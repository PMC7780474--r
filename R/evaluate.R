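# Evaluation toolkit: landmark sampling curves, Procrustean fit between
# datasets, random-skewers covariance correspondence.

# PROTEST-style fit between two specimen score matrices: columns are centered,
# each matrix scaled to unit total sum of squares, and the fit is the sum of
# singular values of X'Y (equivalently sqrt(1 - m^2) of the Procrustean
# superimposition). 1 means identical configurations of specimens in
# morphospace; 0 means no correspondence.
.protestFit <- function(X, Y) {
  p <- max(ncol(X), ncol(Y))
  pad <- function(M) {
    if (ncol(M) < p) M <- cbind(M, matrix(0, nrow(M), p - ncol(M)))
    M
  }
  X <- pad(as.matrix(X))
  Y <- pad(as.matrix(Y))
  X <- sweep(X, 2L, colMeans(X))
  Y <- sweep(Y, 2L, colMeans(Y))
  nx <- sqrt(sum(X^2))
  ny <- sqrt(sum(Y^2))
  if (nx == 0 || ny == 0) stop("zero-variance score matrix")
  min(sum(svd(crossprod(X / nx, Y / ny))$d), 1)
}

#' Landmark sampling curve (sampling sufficiency)
#'
#' Subsamples the point set at sizes `k = 3, 4, ..., n_points`, re-aligns each
#' subsample (GPA), and measures the fit of the subsampled dataset to the full
#' dataset as the Procrustean correlation between the specimen score matrices
#' (fit concerns the positions of specimens in morphospace, not the spatial
#' positions of points). A plateau in the median curve signifies stationarity
#' in the characterization of shape variation; the smallest `k` whose median
#' fit reaches 0.90 / 0.95 / 0.99 is reported.
#'
#' @param aligned an [AlignmentResult-class] of the full dataset.
#' @param iterations number of random subsampling iterations per `k`.
#' @param seed integer seed.
#' @param thresholds numeric fit thresholds to locate.
#' @param realign logical; `TRUE` re-runs GPA on every subsample (the proper
#'   procedure), `FALSE` subsets the already-aligned coordinates (cheaper).
#' @param k_values optional integer vector of subset sizes (default `3:n`).
#' @return list of class `samplingCurve`: `k` (sizes), `fits`
#'   (iterations x length(k) matrix), `median_fit`, `k_at_fit` (named vector),
#'   and quantile bands `q05`, `q95`.
#' @export
samplingCurve <- function(aligned, iterations = 100L, seed = 1L,
                          thresholds = c(0.90, 0.95, 0.99), realign = TRUE,
                          k_values = NULL) {
  if (iterations < 1L) stop("iterations must be >= 1")
  arr <- aligned@aligned
  K <- dim(arr)[1L]
  if (K < 4L) stop("need at least 4 points")
  if (is.null(k_values)) k_values <- 3:K
  set.seed(seed)
  fullScores <- aligned@pca$scores
  fits <- matrix(NA_real_, iterations, length(k_values))
  for (it in seq_len(iterations)) {
    for (j in seq_along(k_values)) {
      k <- k_values[j]
      rows <- if (k == K) seq_len(K) else sort(sample.int(K, k))
      sub <- arr[rows, , , drop = FALSE]
      scores <- if (realign && k >= 3L) {
        gpa(sub)@pca$scores
      } else {
        t(apply(sub, 3L, as.vector))
      }
      fits[it, j] <- .protestFit(fullScores, scores)
    }
  }
  med <- apply(fits, 2L, median)
  k_at <- vapply(thresholds, function(th) {
    hit <- which(med >= th)
    if (length(hit)) k_values[hit[1L]] else NA_integer_
  }, 1L)
  names(k_at) <- sprintf("%.2f", thresholds)
  structure(
    list(
      k = k_values, fits = fits, median_fit = med,
      q05 = apply(fits, 2L, quantile, 0.05),
      q95 = apply(fits, 2L, quantile, 0.95),
      k_at_fit = k_at
    ),
    class = "samplingCurve"
  )
}

#' @export
print.samplingCurve <- function(x, ...) {
  cat(sprintf(
    "samplingCurve: k = %d..%d; median fit at k_max = %.4f; k at fit {%s}\n",
    min(x$k), max(x$k), x$median_fit[length(x$median_fit)],
    paste(sprintf("%s: %s", names(x$k_at_fit), x$k_at_fit), collapse = ", ")
  ))
  invisible(x)
}

#' Write a sampling curve to CSV and a JSON summary
#'
#' @param x a [samplingCurve()] result.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return `invisible(x)`.
#' @export
writeSamplingCurve <- function(x, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    write.csv(data.frame(
      k = x$k, median_fit = x$median_fit, q05 = x$q05, q95 = x$q95
    ), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(k_at_fit = as.list(x$k_at_fit)), json_path,
      auto_unbox = TRUE
    )
  }
  invisible(x)
}

#' Procrustean fit between two aligned datasets
#'
#' Least-squares superimposition of the specimen score matrices of two
#' alignments of the same specimens (e.g. a landmark-only and a full
#' semilandmark dataset), with a permutation test on specimen rows. Fit is
#' `sqrt(1 - ss_residual / ss_total)`, 1 for identical morphospace
#' configurations.
#'
#' @param a,b [AlignmentResult-class] objects over the same specimens.
#' @param permutations number of row permutations for the p-value.
#' @param seed integer seed.
#' @return list with `fit` and `p_value`.
#' @export
fitBetweenDatasets <- function(a, b, permutations = 999L, seed = 1L) {
  ia <- dimnames(a@aligned)[[3L]]
  ib <- dimnames(b@aligned)[[3L]]
  if (!setequal(ia, ib)) stop("datasets cover different specimens")
  X <- a@pca$scores
  Y <- b@pca$scores[match(ia, ib), , drop = FALSE]
  fit <- .protestFit(X, Y)
  set.seed(seed)
  n <- nrow(X)
  exceed <- 0L
  for (i in seq_len(permutations)) {
    if (.protestFit(X, Y[sample.int(n), , drop = FALSE]) >= fit) exceed <- exceed + 1L
  }
  list(fit = fit, p_value = (exceed + 1L) / (permutations + 1L))
}

#' Random-skewers correspondence between two covariance matrices
#'
#' Applies the same random selection vectors (uniform on the unit sphere) to
#' both covariance matrices and averages the cosine between the response
#' vectors. 1 means proportional responses (scale-invariant); the p-value is
#' the probability that the cosine of two independent random unit vectors in
#' the same dimension exceeds the observed correspondence.
#'
#' @param cov_a,cov_b symmetric PSD matrices of equal dimension.
#' @param n_iterations number of skewers.
#' @param seed integer seed.
#' @return list of class `skewersResult` with `correspondence`, `p_value`,
#'   `n_iterations`.
#' @export
randomSkewers <- function(cov_a, cov_b, n_iterations = 10000L, seed = 1L) {
  cov_a <- as.matrix(cov_a)
  cov_b <- as.matrix(cov_b)
  if (!all(dim(cov_a) == dim(cov_b))) stop("covariance matrices differ in dimension")
  p <- nrow(cov_a)
  set.seed(seed)
  S <- matrix(rnorm(p * n_iterations), p, n_iterations)
  S <- sweep(S, 2L, sqrt(colSums(S^2)), "/")
  RA <- cov_a %*% S
  RB <- cov_b %*% S
  num <- colSums(RA * RB)
  den <- sqrt(colSums(RA^2) * colSums(RB^2))
  ok <- den > 0
  correspondence <- mean(num[ok] / den[ok])
  # null: cosine of two independent uniform unit vectors in dimension p
  U1 <- matrix(rnorm(p * n_iterations), p, n_iterations)
  U2 <- matrix(rnorm(p * n_iterations), p, n_iterations)
  nullcos <- colSums(U1 * U2) / sqrt(colSums(U1^2) * colSums(U2^2))
  structure(
    list(
      correspondence = correspondence,
      p_value = max(mean(nullcos >= correspondence), 1 / n_iterations),
      n_iterations = n_iterations
    ),
    class = "skewersResult"
  )
}

#' @export
print.skewersResult <- function(x, ...) {
  cat(sprintf(
    "randomSkewers: correspondence = %.4f (p = %.4g, %d iterations)\n",
    x$correspondence, x$p_value, x$n_iterations
  ))
  invisible(x)
}

#' Trait covariance matrix of an alignment
#'
#' Covariance of the vectorized aligned coordinates (3k columns), scaled by
#' `1/(n-1)`.
#'
#' @param result an [AlignmentResult-class].
#' @return numeric 3k x 3k matrix.
#' @export
traitCovariance <- function(result) {
  flat <- t(apply(result@aligned, 3L, as.vector))
  stats::cov(flat)
}
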