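#' Represent an absent structure as a negligible region
#'
#' When a region is missing from a specimen (e.g. a variably present bone),
#' its surface points are replaced by `n` identical coordinates at an anchor
#' position on an adjacent structure — a region of zero (after joint
#' alignment, near-zero) size that still carries positional information.
#' `n` must equal the surface-point count of the region in the patched
#' specimens so that configurations stay commensurate.
#'
#' @param anchor numeric 3-vector, the representative position.
#' @param n integer >= 1, number of replicated points.
#' @param labels character vector of length `n`, the region's surface-point
#'   labels.
#' @param region region name for the replicated points.
#' @return A [LandmarkConfig-class] fragment (surface-class points only) for
#'   insertion in canonical order via [appendPoints()].
#' @export
makeNegligibleRegion <- function(anchor, n, labels, region = "negligible") {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (length(labels) != n) {
    stop(sprintf("n = %d does not match the %d region labels", n, length(labels)))
  }
  LandmarkConfig(
    "",
    data.frame(
      label = labels, class = "surface", region = region,
      curve_id = NA_character_, ordinal = NA_integer_, side = "none",
      stringsAsFactors = FALSE
    ),
    matrix(rep(as.numeric(anchor), each = n), n, 3L)
  )
}

#' Insert points of one configuration into another
#'
#' @param config a [LandmarkConfig-class].
#' @param fragment a [LandmarkConfig-class] whose points are inserted.
#' @param after label in `config` after which to insert (default: append at
#'   the end).
#' @return The combined [LandmarkConfig-class].
#' @export
appendPoints <- function(config, fragment, after = NULL) {
  pos <- if (is.null(after)) {
    nrow(config@points)
  } else {
    match(after, config@points$label)
  }
  if (is.na(pos)) stop("label not found: ", after)
  idx <- seq_len(nrow(config@points))
  before <- idx[idx <= pos]
  rest <- idx[idx > pos]
  pts <- rbind(
    config@points[before, , drop = FALSE],
    fragment@points,
    config@points[rest, , drop = FALSE]
  )
  xyz <- rbind(
    config@coords[before, , drop = FALSE],
    fragment@coords,
    config@coords[rest, , drop = FALSE]
  )
  cfg <- LandmarkConfig(config@specimenId, pts, xyz)
  validObject(cfg)
  cfg
}

#' Fence off a negligibly sized hole
#'
#' Specimens lacking a fossa or foramen that other specimens possess receive
#' a minuscule fenced-off area — approximately the size of one surface point —
#' built from the same landmarks and curve labels used to fence the real
#' hole. All specimens can then share one atlas, and the non-comparable fence
#' labels are removed after patching ([dropPoints()]).
#'
#' @param mesh specimen [TriMesh-class].
#' @param position numeric 3-vector on (or near) the region surface, away
#'   from real boundary curves.
#' @param surface_point_spacing scalar > 0; the fence circle's diameter.
#' @param curve_id label for the fence curve.
#' @param anchor_label label of the fence anchor landmark.
#' @param n_points number of fence curve points (anchor excluded).
#' @param region region name.
#' @return list with `fragment` (a [LandmarkConfig-class] holding the anchor
#'   landmark plus the closed fence curve, all points on the mesh surface) and
#'   `curve` (the matching [curveDefinition()] row).
#' @export
makeNegligibleHole <- function(mesh, position, surface_point_spacing,
                               curve_id = "fence", anchor_label = "fence_anchor",
                               n_points = 23L, region = "all") {
  if (surface_point_spacing <= 0) stop("surface_point_spacing must be positive")
  np <- nearestPointOnMesh(mesh, position)
  center <- np$point[1L, ]
  nrm <- .faceNormals(mesh@vertices, mesh@faces)[np$face[1L], ]
  a <- if (abs(nrm[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- a - sum(a * nrm) * nrm
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(
    nrm[2L] * t1[3L] - nrm[3L] * t1[2L],
    nrm[3L] * t1[1L] - nrm[1L] * t1[3L],
    nrm[1L] * t1[2L] - nrm[2L] * t1[1L]
  )
  radius <- surface_point_spacing / 2
  theta <- seq(0, 2 * pi, length.out = n_points + 2L)[seq_len(n_points + 1L)]
  circle <- t(vapply(theta, function(th) {
    center + radius * (cos(th) * t1 + sin(th) * t2)
  }, numeric(3L)))
  circle <- nearestPointOnMesh(mesh, circle)$point
  pts <- data.frame(
    label = c(anchor_label, sprintf("%s_%02d", curve_id, seq_len(n_points))),
    class = c("landmark", rep("curve", n_points)),
    region = region,
    curve_id = c(NA_character_, rep(curve_id, n_points)),
    ordinal = c(NA_integer_, seq_len(n_points) - 1L),
    side = "none", stringsAsFactors = FALSE
  )
  fragment <- LandmarkConfig("", pts, circle)
  curve <- curveDefinition(curve_id, anchor_label, anchor_label,
    n_points + 2L,
    closed = TRUE
  )
  list(fragment = fragment, curve = curve)
}
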