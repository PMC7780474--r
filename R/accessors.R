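#' Construct a TriMesh
#'
#' Builds a [TriMesh-class] from raw vertices and faces, making face winding
#' globally consistent (where orientable), orienting normals outward by a
#' centroid heuristic, and computing area-weighted unit vertex normals.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates.
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param dialect character tag recording where the geometry came from.
#' @param fixWinding logical; propagate a consistent winding from a seed face.
#' @return A [TriMesh-class].
#' @examples
#' m <- TriMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1L, 2L, 3L)))
#' nVertices(m)
#' @export
TriMesh <- function(vertices, faces, dialect = "constructed", fixWinding = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  colnames(vertices) <- c("x", "y", "z")
  if (is.null(faces) || length(faces) == 0L) {
    faces <- matrix(integer(0), 0L, 3L)
  } else {
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
  }
  orientable <- TRUE
  if (nrow(faces) > 1L && fixWinding) {
    fw <- .consistentWinding(faces)
    faces <- fw$faces
    orientable <- fw$orientable
    if (!orientable) {
      warning("mesh is not orientable; face winding left as per-component majority")
    }
  }
  if (nrow(faces) > 0L) {
    faces <- .orientOutward(vertices, faces)
  }
  vn <- .vertexNormals(vertices, faces)
  new("TriMesh",
    vertices = vertices, faces = faces, vertexNormals = vn,
    orientable = orientable, dialect = dialect
  )
}

#' Construct a LandmarkConfig
#'
#' @param specimenId character specimen identifier.
#' @param points data.frame with columns `label`, `class`, `region`,
#'   `curve_id`, `ordinal`, `side`; missing optional columns are filled.
#' @param coords numeric n x 3 matrix.
#' @return A [LandmarkConfig-class].
#' @export
LandmarkConfig <- function(specimenId, points, coords) {
  points <- as.data.frame(points, stringsAsFactors = FALSE)
  if (is.null(points$region)) points$region <- "all"
  if (is.null(points$curve_id)) points$curve_id <- NA_character_
  if (is.null(points$ordinal)) points$ordinal <- NA_integer_
  if (is.null(points$side)) points$side <- "none"
  points$label <- as.character(points$label)
  points$class <- as.character(points$class)
  points$region <- as.character(points$region)
  points$curve_id <- as.character(points$curve_id)
  points$ordinal <- as.integer(points$ordinal)
  points$side <- as.character(points$side)
  points <- points[, c("label", "class", "region", "curve_id", "ordinal", "side")]
  rownames(points) <- NULL
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- list(points$label, c("x", "y", "z"))
  new("LandmarkConfig", specimenId = as.character(specimenId), points = points, coords = coords)
}

#' @describeIn TriMesh-class number of vertices
#' @param mesh,x object
#' @export
nVertices <- function(mesh) nrow(mesh@vertices)

#' @describeIn TriMesh-class number of faces
#' @export
nFaces <- function(mesh) nrow(mesh@faces)

#' @describeIn TriMesh-class vertex coordinate matrix
#' @export
vertices <- function(mesh) mesh@vertices

#' @describeIn TriMesh-class face index matrix (1-based)
#' @export
faces <- function(mesh) mesh@faces

#' @describeIn TriMesh-class unit vertex normals
#' @export
vertexNormals <- function(mesh) mesh@vertexNormals

#' Coordinates of a configuration
#' @param x a [LandmarkConfig-class].
#' @return numeric n x 3 matrix with label rownames.
#' @export
coords <- function(x) x@coords

#' Point metadata of a configuration
#' @param x a [LandmarkConfig-class].
#' @return data.frame in canonical point order.
#' @export
pointInfo <- function(x) x@points

#' Specimen identifier
#' @param x a [LandmarkConfig-class].
#' @export
specimenId <- function(x) x@specimenId

#' Replace the coordinates of a configuration
#' @param x a [LandmarkConfig-class].
#' @param value numeric n x 3 matrix.
#' @export
`coords<-` <- function(x, value) {
  value <- as.matrix(value)
  stopifnot(nrow(value) == nrow(x@coords), ncol(value) == 3L)
  storage.mode(value) <- "double"
  dimnames(value) <- dimnames(x@coords)
  x@coords <- value
  x
}

#' Centroid size of a point matrix or configuration
#'
#' Root of the summed squared distances of the points to their centroid --
#' the scale measure removed by Procrustes alignment.
#'
#' @param x numeric n x 3 matrix or [LandmarkConfig-class].
#' @return numeric scalar.
#' @export
centroidSize <- function(x) {
  m <- if (is(x, "LandmarkConfig")) x@coords else as.matrix(x)
  m <- sweep(m, 2L, colMeans(m))
  sqrt(sum(m^2))
}

#' @describeIn AlignmentResult-class aligned k x 3 x n array
#' @param result an [AlignmentResult-class].
#' @export
alignedArray <- function(result) result@aligned

#' @describeIn AlignmentResult-class mean shape (k x 3, unit centroid size)
#' @export
meanShape <- function(result) result@meanShape

#' @describeIn AlignmentResult-class original centroid sizes
#' @export
centroidSizes <- function(result) result@centroidSizes

#' @describeIn AlignmentResult-class PCA scores (n specimens x components)
#' @export
pcaScores <- function(result) result@pca$scores

#' @describeIn AlignmentResult-class PCA eigenvalues
#' @export
pcaValues <- function(result) result@pca$values

setMethod("show", "TriMesh", function(object) {
  cat(sprintf(
    "TriMesh: %d vertices, %d faces (%s%s)\n",
    nVertices(object), nFaces(object), object@dialect,
    if (object@orientable) "" else ", non-orientable"
  ))
})

setMethod("show", "LandmarkConfig", function(object) {
  tab <- table(object@points$class)
  cat(sprintf(
    "LandmarkConfig '%s': %d points (%s)\n",
    object@specimenId, nrow(object@points),
    paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", ")
  ))
})

setMethod("show", "Atlas", function(object) {
  cat(sprintf(
    "Atlas: template with %d faces; %d fixed points, %d surface points, %d curves, %d regions\n",
    nFaces(object@mesh),
    sum(object@config@points$class != "surface"),
    sum(object@config@points$class == "surface"),
    nrow(object@curves), length(object@regionMap)
  ))
})

setMethod("show", "TPSModel", function(object) {
  cat(sprintf(
    "TPSModel: k = %d, lambda = %g, nonaffine norm = %.4g\n",
    nrow(object@sourcePoints), object@lambda,
    sqrt(sum(object@nonaffineWeights^2))
  ))
})

setMethod("show", "PatchResult", function(object) {
  if (object@failed) {
    cat(sprintf("PatchResult: FAILED (%s)\n", object@reason))
  } else {
    cat(sprintf(
      "PatchResult: %d surface points placed; max distance-to-surface %.3g; %d internal-side, %d off-region\n",
      nrow(object@diagnostics), max(c(0, object@diagnostics$distance)),
      sum(object@diagnostics$normalAgreement < 0),
      sum(object@diagnostics$offRegion)
    ))
  }
})

setMethod("show", "AlignmentResult", function(object) {
  d <- dim(object@aligned)
  ev <- object@pca$values
  cat(sprintf(
    "AlignmentResult: %d specimens x %d points; PC1-4 cumulative variance %.1f%%\n",
    d[3L], d[1L],
    100 * sum(ev[seq_len(min(4L, length(ev)))]) / sum(ev)
  ))
})
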