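# Internal mesh helpers: winding propagation, outward orientation, normals.

# Unit face normals and (doubled) face areas.
.faceNormals <- function(vertices, faces, normalize = TRUE) {
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  c_ <- vertices[faces[, 3L], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  n <- cbind(
    e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
    e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
    e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  )
  if (!normalize) return(n)
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# Make face winding consistent by breadth-first propagation across shared
# edges. Returns possibly flipped faces and an orientability flag: a mesh is
# flagged non-orientable when propagation demands both orientations for one
# face, or when an edge is shared by more than two faces.
.consistentWinding <- function(faces) {
  m <- nrow(faces)
  # directed edges per face: (1,2), (2,3), (3,1)
  ea <- cbind(faces[, 1L], faces[, 2L], faces[, 3L])
  eb <- cbind(faces[, 2L], faces[, 3L], faces[, 1L])
  from <- as.vector(ea)
  to <- as.vector(eb)
  fid <- rep.int(seq_len(m), 3L)
  key <- paste(pmin(from, to), pmax(from, to))
  # orientation of the directed edge relative to the undirected key
  fwd <- from < to
  grp <- split(seq_along(key), key)
  orientable <- TRUE
  # adjacency: for every manifold edge shared by two faces, record whether the
  # two incident faces currently agree (opposite directed edges = consistent)
  nb <- vector("list", m)
  consist <- vector("list", m)
  for (idx in grp) {
    if (length(idx) == 2L) {
      f1 <- fid[idx[1L]]; f2 <- fid[idx[2L]]
      agree <- fwd[idx[1L]] != fwd[idx[2L]]
      nb[[f1]] <- c(nb[[f1]], f2); consist[[f1]] <- c(consist[[f1]], agree)
      nb[[f2]] <- c(nb[[f2]], f1); consist[[f2]] <- c(consist[[f2]], agree)
    } else if (length(idx) > 2L) {
      orientable <- FALSE
    }
  }
  flip <- rep(NA, m)
  for (seed in seq_len(m)) {
    if (!is.na(flip[seed])) next
    flip[seed] <- FALSE
    queue <- seed
    while (length(queue)) {
      f <- queue[[1L]]
      queue <- queue[-1L]
      ns <- nb[[f]]
      if (is.null(ns)) next
      want <- ifelse(consist[[f]], flip[f], !flip[f])
      for (j in seq_along(ns)) {
        g <- ns[[j]]
        if (is.na(flip[g])) {
          flip[g] <- want[[j]]
          queue <- c(queue, g)
        } else if (flip[g] != want[[j]]) {
          orientable <- FALSE
        }
      }
    }
  }
  if (any(flip)) faces[flip, ] <- faces[flip, c(1L, 3L, 2L)]
  list(faces = faces, orientable = orientable)
}

# Flip all faces when normals point inward on average (centroid heuristic).
.orientOutward <- function(vertices, faces) {
  fn <- .faceNormals(vertices, faces, normalize = FALSE)
  centers <- (vertices[faces[, 1L], , drop = FALSE] +
    vertices[faces[, 2L], , drop = FALSE] +
    vertices[faces[, 3L], , drop = FALSE]) / 3
  out <- sweep(centers, 2L, colMeans(vertices))
  if (sum(fn * out) < 0) faces <- faces[, c(1L, 3L, 2L), drop = FALSE]
  faces
}

# Area-weighted unit vertex normals (cross products are already area-weighted).
.vertexNormals <- function(vertices, faces) {
  vn <- matrix(0, nrow(vertices), 3L)
  if (nrow(faces) > 0L) {
    fn <- .faceNormals(vertices, faces, normalize = FALSE)
    for (j in 1:3) {
      for (cc in 1:3) {
        acc <- rowsum(fn[, cc], faces[, j], reorder = FALSE)
        vn[as.integer(rownames(acc)), cc] <- vn[as.integer(rownames(acc)), cc] + acc[, 1L]
      }
    }
  }
  len <- sqrt(rowSums(vn^2))
  nz <- len > 0
  vn[nz, ] <- vn[nz, , drop = FALSE] / len[nz]
  colnames(vn) <- c("nx", "ny", "nz")
  vn
}

.bboxDiagonal <- function(vertices) {
  rng <- apply(vertices, 2L, range)
  sqrt(sum((rng[2L, ] - rng[1L, ])^2))
}
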