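#' Center a mesh at the origin
#'
#' Translates the mesh so the vertex centroid sits at the origin. Shape is
#' unchanged; the operation is idempotent. Specimen meshes are centered before
#' digitizing so the mesh can be rotated comfortably in landmarking software.
#'
#' @param mesh a [TriMesh-class] with at least one vertex.
#' @return The centered [TriMesh-class].
#' @export
centerMesh <- function(mesh) {
  if (nVertices(mesh) == 0L) stop("cannot center an empty mesh")
  mesh@vertices <- sweep(mesh@vertices, 2L, colMeans(mesh@vertices))
  mesh
}

#' Nearest point on a mesh surface
#'
#' Global closest point over all closed triangles of the mesh, for one or
#' several query points. Used as the fallback projection target during
#' patching when ray casting finds no surface.
#'
#' @param mesh a [TriMesh-class] with at least one face.
#' @param query numeric 3-vector or m x 3 matrix of query points.
#' @return A list with `point` (m x 3 matrix of surface points), `face`
#'   (1-based face index per query) and `distance`.
#' @export
nearestPointOnMesh <- function(mesh, query) {
  if (nFaces(mesh) == 0L) stop("mesh has no faces")
  q <- if (is.null(dim(query))) matrix(query, 1L, 3L) else as.matrix(query)
  storage.mode(q) <- "double"
  cpp_closest_points(mesh@vertices, mesh@faces, q)
}

#' Intersections of a line with a mesh
#'
#' Casts an infinite line through `origin` along the unit vector `direction`
#' and reports every triangle intersection, in both the forward and backward
#' senses, ordered by absolute signed distance. Each hit carries the sign of
#' the dot product between the face normal and the ray direction, used to
#' diagnose placements on the reverse side of polygons (face inversion).
#'
#' @param mesh a [TriMesh-class].
#' @param origin numeric 3-vector.
#' @param direction numeric unit 3-vector.
#' @return data.frame with columns `x`, `y`, `z`, `t` (signed distance along
#'   `direction`), `face`, `normal_dot`; zero rows when there is no hit.
#' @export
rayMeshIntersections <- function(mesh, origin, direction) {
  stopifnot(length(origin) == 3L, length(direction) == 3L)
  nl <- sqrt(sum(direction^2))
  if (abs(nl - 1) > 1e-6) stop("direction must be a unit vector")
  h <- cpp_ray_hits(mesh@vertices, mesh@faces, as.double(origin), as.double(direction))
  o <- order(abs(h$t))
  data.frame(
    x = h$point[o, 1L], y = h$point[o, 2L], z = h$point[o, 3L],
    t = h$t[o], face = h$face[o], normal_dot = h$normal_dot[o]
  )
}

#' Extract a sub-mesh by face selection
#'
#' Keeps the selected faces and the vertices they reference, re-indexed to a
#' compact mesh. Original face indices are recorded in the `sourceFaces`
#' attribute for traceback. Intended use: temporarily delete interfering
#' nearby surfaces (teeth, internal walls) before patching, then restore the
#' full mesh for sliding.
#'
#' @param mesh a [TriMesh-class].
#' @param keep integer/logical face index vector, or a predicate taking the
#'   m x 3 matrix of face centroids and returning a logical vector.
#' @return A [TriMesh-class] with attribute `sourceFaces`.
#' @export
extractSubmesh <- function(mesh, keep) {
  f <- mesh@faces
  if (is.function(keep)) {
    centers <- (mesh@vertices[f[, 1L], , drop = FALSE] +
      mesh@vertices[f[, 2L], , drop = FALSE] +
      mesh@vertices[f[, 3L], , drop = FALSE]) / 3
    keep <- keep(centers)
  }
  idx <- if (is.logical(keep)) which(keep) else as.integer(keep)
  if (length(idx) == 0L) stop("empty face selection")
  if (any(idx < 1L | idx > nrow(f))) stop("face selection out of range")
  fs <- f[idx, , drop = FALSE]
  used <- sort(unique(as.vector(fs)))
  remap <- integer(nVertices(mesh))
  remap[used] <- seq_along(used)
  sub <- TriMesh(mesh@vertices[used, , drop = FALSE],
    matrix(remap[fs], ncol = 3L),
    dialect = mesh@dialect, fixWinding = FALSE
  )
  attr(sub, "sourceFaces") <- idx
  sub
}
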