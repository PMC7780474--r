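#' @import methods
#' @importFrom stats dist prcomp rnorm runif sd var quantile median cor
#' @importFrom utils read.csv write.csv head
#' @useDynLib semiland, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' TriMesh: a triangle surface mesh
#'
#' Container for a triangulated surface: specimen or template geometry as used
#' throughout the patching and sliding pipeline. Vertex normals are derived
#' (area-weighted average of incident face normals) and face winding is made
#' globally consistent on construction where the mesh is orientable.
#'
#' @slot vertices numeric matrix, n x 3, vertex coordinates in mesh units.
#' @slot faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @slot vertexNormals numeric matrix, n x 3, unit vertex normals (zero rows
#'   for vertices that belong to no face).
#' @slot orientable logical; `TRUE` when a globally consistent winding was
#'   found by propagation from a seed face.
#' @slot dialect character; source file dialect (`"ply_ascii"`,
#'   `"ply_binary_le"`, `"ply_binary_be"`, `"stl_ascii"`, `"stl_binary"`, or
#'   `"constructed"`).
#' @seealso [TriMesh()], [readMesh()], [writeMesh()]
#' @export
setClass("TriMesh",
  representation(
    vertices = "matrix",
    faces = "matrix",
    vertexNormals = "matrix",
    orientable = "logical",
    dialect = "character"
  )
)

setValidity("TriMesh", function(object) {
  v <- object@vertices
  f <- object@faces
  if (!is.numeric(v) || ncol(v) != 3L) return("vertices must be an n x 3 numeric matrix")
  if (nrow(v) < 1L) return("mesh must have at least one vertex")
  if (nrow(f) > 0L) {
    if (ncol(f) != 3L) return("faces must be an m x 3 index matrix")
    if (any(f < 1L) || any(f > nrow(v))) return("face indices out of range")
    if (any(f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L]))
      return("faces must reference 3 distinct vertices")
  }
  if (anyNA(v)) return("vertex coordinates contain NA")
  TRUE
})

#' LandmarkConfig: an ordered point configuration for one specimen
#'
#' Each point carries a unique label, a class (`landmark`, `curve`, or
#' `surface`), a region, optional curve membership (`curve_id`, 0-based
#' `ordinal` along the curve) and a `side` (`left`, `right`, `midline`,
#' `none`). Point order is the canonical order shared by all configurations
#' entering a joint analysis.
#'
#' @slot specimenId character scalar.
#' @slot points data.frame with columns `label`, `class`, `region`,
#'   `curve_id`, `ordinal`, `side` (one row per point, canonical order).
#' @slot coords numeric matrix, n x 3.
#' @seealso [LandmarkConfig()], [readConfigurations()], [dropPoints()]
#' @export
setClass("LandmarkConfig",
  representation(
    specimenId = "character",
    points = "data.frame",
    coords = "matrix"
  )
)

setValidity("LandmarkConfig", function(object) {
  pts <- object@points
  need <- c("label", "class", "region", "curve_id", "ordinal", "side")
  if (!all(need %in% names(pts))) {
    return(paste("points data.frame must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(pts) != nrow(object@coords)) return("points and coords row counts differ")
  if (ncol(object@coords) != 3L) return("coords must be n x 3")
  if (anyDuplicated(pts$label)) return("point labels must be unique")
  if (!all(pts$class %in% c("landmark", "curve", "surface"))) {
    return("class must be one of landmark, curve, surface")
  }
  is_curve <- pts$class == "curve"
  if (any(is_curve & (is.na(pts$curve_id) | is.na(pts$ordinal)))) {
    return("curve points must carry curve_id and ordinal")
  }
  if (any(!is_curve & !is.na(pts$curve_id))) {
    return("curve_id is only allowed on curve-class points")
  }
  for (cid in unique(pts$curve_id[is_curve])) {
    o <- sort(pts$ordinal[is_curve & pts$curve_id %in% cid])
    if (!identical(as.integer(o), seq_along(o) - 1L)) {
      return(sprintf("ordinals within curve '%s' must be consecutive from 0", cid))
    }
  }
  TRUE
})

#' Atlas: a template mesh bound to its point configuration
#'
#' The source of surface semilandmarks during patching. Fixed points
#' (landmarks and curve points) must be in one-to-one label correspondence
#' with every specimen to be patched.
#'
#' @slot mesh a [TriMesh-class] template mesh.
#' @slot config a [LandmarkConfig-class] with landmarks, resampled curve
#'   points and surface points, all on the template surface.
#' @slot curves data.frame of curve definitions with columns `curve_id`,
#'   `start_landmark`, `end_landmark`, `n_points`, `closed`.
#' @slot regionMap named list mapping region name to the surface-point labels
#'   it contains.
#' @seealso [buildAtlas()], [placePatch()]
#' @export
setClass("Atlas",
  representation(
    mesh = "TriMesh",
    config = "LandmarkConfig",
    curves = "data.frame",
    regionMap = "list"
  )
)

#' TPSModel: a fitted 3D thin-plate spline
#'
#' Mapping between two labelled point sets, exposing warping of arbitrary
#' probes and the bending-energy quadratic form. With `lambda = 0` the map
#' interpolates the targets exactly; `lambda > 0` gives a smoothing fit.
#'
#' @slot sourcePoints numeric k x 3 source configuration.
#' @slot targetPoints numeric k x 3 target configuration.
#' @slot nonaffineWeights numeric k x 3; columns orthogonal to the affine
#'   subspace of the sources.
#' @slot affine numeric 4 x 3; rows are intercept then the linear map, so a
#'   probe row p maps affinely to `c(1, p) %*% affine`.
#' @slot kernelMatrix numeric k x k radial kernel evaluated at source
#'   inter-point distances (sign fixed so the bending form is PSD).
#' @slot bendingEnergyMatrix numeric k x k symmetric PSD matrix annihilating
#'   affine configurations (rank at most k - 4).
#' @slot lambda numeric regularization parameter (>= 0).
#' @seealso [fitTPS()], [warpPoints()], [bendingEnergy()]
#' @export
setClass("TPSModel",
  representation(
    sourcePoints = "matrix",
    targetPoints = "matrix",
    nonaffineWeights = "matrix",
    affine = "matrix",
    kernelMatrix = "matrix",
    bendingEnergyMatrix = "matrix",
    lambda = "numeric"
  )
)

#' PatchResult: outcome of projecting template surface points on a specimen
#'
#' Patch failure is represented as a value (`failed = TRUE` with a reason),
#' not an exception, so batch runs complete and report.
#'
#' @slot config [LandmarkConfig-class] holding the specimen fixed points plus
#'   newly placed surface points in canonical order.
#' @slot diagnostics data.frame (one row per surface point) with columns
#'   `label`, `distance` (to the specimen surface), `normalAgreement` (+1 when
#'   the hit face normal opposes the projection ray, i.e. an external-surface
#'   placement; -1 for internal-surface capture), `method` (`ray_neg`,
#'   `ray_pos`, `nearest`), and `offRegion`.
#' @slot failed logical scalar.
#' @slot reason character; empty when `failed` is `FALSE`.
#' @seealso [placePatch()], [piecemealPatch()]
#' @export
setClass("PatchResult",
  representation(
    config = "LandmarkConfig",
    diagnostics = "data.frame",
    failed = "logical",
    reason = "character"
  )
)

#' AlignmentResult: generalized Procrustes alignment plus PCA
#'
#' @slot aligned numeric array k x 3 x n of aligned configurations (centered,
#'   unit centroid size, optimally rotated), dimnames: point labels, xyz,
#'   specimen ids.
#' @slot points data.frame of point metadata (canonical order) carried over
#'   from the input configurations.
#' @slot meanShape numeric k x 3 mean shape, unit centroid size.
#' @slot centroidSizes named numeric vector of original centroid sizes.
#' @slot pca list with elements `values` (eigenvalues), `vectors`
#'   (3k x r loadings) and `scores` (n x r specimen scores).
#' @seealso [gpa()], [findMeanSpec()], [samplingCurve()]
#' @export
setClass("AlignmentResult",
  representation(
    aligned = "array",
    points = "data.frame",
    meanShape = "matrix",
    centroidSizes = "numeric",
    pca = "list"
  )
)
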