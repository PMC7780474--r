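#' Impute a missing side by mirroring across the midline plane
#'
#' Bilaterally symmetric structures are often digitized on one side only, but
#' Procrustes alignment of one-sided data exaggerates shape variation along
#' the midline. This fills the missing side of each bilateral pair by
#' reflecting its present partner across the least-squares plane through the
#' midline points. The mirrored labels are typically removed again after
#' alignment (see [dropPoints()]).
#'
#' @param config a [LandmarkConfig-class]; missing-side points carry `NA`
#'   coordinates.
#' @param pairs two-column matrix or data.frame of (left, right) labels; each
#'   pair must have exactly one present (non-`NA`) side.
#' @param midline_labels character labels of at least 3 non-collinear midline
#'   points.
#' @return The completed [LandmarkConfig-class] (canonical order preserved).
#' @export
mirrorFill <- function(config, pairs, midline_labels) {
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L)
  xyz <- config@coords
  mid <- xyz[midline_labels, , drop = FALSE]
  if (nrow(mid) < 3L) stop("need at least 3 midline points")
  if (anyNA(mid)) stop("midline points must all be present")
  ctr <- colMeans(mid)
  sv <- svd(sweep(mid, 2L, ctr))
  if (sv$d[2L] < 1e-12 * sv$d[1L]) stop("midline points are collinear; cannot fit a plane")
  normal <- sv$v[, 3L]
  reflect <- function(p) p - 2 * sum((p - ctr) * normal) * normal
  for (i in seq_len(nrow(pairs))) {
    l <- pairs[i, 1L]
    r <- pairs[i, 2L]
    if (!all(c(l, r) %in% rownames(xyz))) stop("pair labels not in configuration: ", l, "/", r)
    lNA <- anyNA(xyz[l, ])
    rNA <- anyNA(xyz[r, ])
    if (lNA == rNA) {
      stop(sprintf("pair (%s, %s) must have exactly one present side", l, r))
    }
    if (lNA) xyz[l, ] <- reflect(xyz[r, ]) else xyz[r, ] <- reflect(xyz[l, ])
  }
  coords(config) <- xyz
  config
}

#' Proportional variance of midline points after alignment
#'
#' Ratio of summed per-coordinate variances of the midline points to the
#' summed variances of a reference point set (by default all `side == "right"`
#' points), computed on Procrustes-aligned coordinates. One-side-only
#' alignment inflates this fraction; mirrored bilateral alignment reduces it.
#'
#' @param result an [AlignmentResult-class].
#' @param midline_labels character labels of midline points.
#' @param reference_labels character labels of the reference set; default all
#'   right-side points in the result's metadata.
#' @return numeric scalar in `[0, Inf)` (in `[0, 1]` when the reference set is
#'   a superset of the midline set).
#' @export
midlineVarianceFraction <- function(result, midline_labels, reference_labels = NULL) {
  if (!length(midline_labels)) stop("empty midline label set")
  arr <- result@aligned
  labels <- dimnames(arr)[[1L]]
  if (!all(midline_labels %in% labels)) stop("unknown midline labels")
  if (is.null(reference_labels)) {
    reference_labels <- result@points$label[result@points$side == "right"]
  }
  if (!length(reference_labels)) stop("empty reference label set")
  if (!all(reference_labels %in% labels)) stop("unknown reference labels")
  pointVar <- function(lbls) {
    sub <- arr[lbls, , , drop = FALSE]
    flat <- t(apply(sub, 3L, as.vector))
    sum(apply(flat, 2L, var))
  }
  denom <- pointVar(reference_labels)
  if (denom <= 0) stop("reference set has zero variance")
  pointVar(midline_labels) / denom
}
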