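#' Read a triangle mesh from PLY or STL
#'
#' Supports ASCII and binary (little- and big-endian) PLY, and ASCII and
#' binary STL. Geometry is identical regardless of dialect (within float32
#' representation for binary encodings); the source dialect is recorded on
#' the returned mesh. Stored normals are ignored and recomputed. STL stores
#' no connectivity, so duplicate vertices are welded within
#' `1e-8 x` bounding-box diagonal on import.
#'
#' @param path file path.
#' @param format_hint optional, one of `"ply"`, `"stl"`; when missing the
#'   format is sniffed from the file header.
#' @return A [TriMesh-class].
#' @examples
#' tmp <- tempfile(fileext = ".ply")
#' writeMesh(TriMesh(diag(3), rbind(c(1L, 2L, 3L))), tmp)
#' readMesh(tmp)
#' @seealso [writeMesh()]
#' @export
readMesh <- function(path, format_hint = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  head_raw <- readBin(path, "raw", n = 512L)
  head_txt <- rawToChar(head_raw[head_raw != as.raw(0L)])
  fmt <- format_hint
  if (is.null(fmt)) {
    fmt <- if (grepl("^ply", head_txt, useBytes = TRUE)) "ply" else "stl"
  }
  fmt <- match.arg(fmt, c("ply", "stl"))
  if (fmt == "ply") .readPLY(path) else .readSTL(path)
}

#' Write a triangle mesh
#'
#' `ply_ascii` writes coordinates at full double precision, so an
#' ascii round trip reproduces the geometry exactly. Binary PLY is written
#' little-endian with float32 coordinates; STL is written binary.
#'
#' @param mesh a [TriMesh-class].
#' @param path output file path.
#' @param dialect one of `"ply_ascii"`, `"ply_binary"`, `"stl"`.
#' @return `invisible(path)`.
#' @seealso [readMesh()]
#' @export
writeMesh <- function(mesh, path, dialect = c("ply_ascii", "ply_binary", "stl")) {
  dialect <- match.arg(dialect)
  switch(dialect,
    ply_ascii = .writePLYascii(mesh, path),
    ply_binary = .writePLYbinary(mesh, path),
    stl = .writeSTLbinary(mesh, path)
  )
  invisible(path)
}

## ---- PLY ----

.plyTypeSize <- c(
  char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
  short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
  int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
  float = 4L, float32 = 4L, double = 8L, float64 = 8L
)

.plyReadScalar <- function(con, type, n, endian) {
  switch(type,
    char = , int8 = readBin(con, "integer", n, size = 1L, signed = TRUE, endian = endian),
    uchar = , uint8 = readBin(con, "integer", n, size = 1L, signed = FALSE, endian = endian),
    short = , int16 = readBin(con, "integer", n, size = 2L, signed = TRUE, endian = endian),
    ushort = , uint16 = readBin(con, "integer", n, size = 2L, signed = FALSE, endian = endian),
    int = , int32 = , uint = , uint32 = readBin(con, "integer", n, size = 4L, endian = endian),
    float = , float32 = readBin(con, "double", n, size = 4L, endian = endian),
    double = , float64 = readBin(con, "double", n, size = 8L, endian = endian),
    stop("unsupported PLY property type: ", type)
  )
}

.readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ASCII lines
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("malformed PLY header: missing 'ply' magic line")
  format <- NULL
  elements <- list()
  cur <- NULL
  lineno <- 1L
  repeat {
    line <- readLines(con, n = 1L)
    lineno <- lineno + 1L
    if (length(line) == 0L) stop("malformed PLY header: no end_header (line ", lineno, ")")
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(tok) == 0L || tok[1L] == "comment" || tok[1L] == "obj_info") next
    if (tok[1L] == "format") {
      format <- tok[2L]
    } else if (tok[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2L], count = as.integer(tok[3L]), props = list())
    } else if (tok[1L] == "property") {
      if (is.null(cur)) stop("malformed PLY header: property before element (line ", lineno, ")")
      if (tok[2L] == "list") {
        cur$props[[tok[5L]]] <- list(list = TRUE, countType = tok[3L], itemType = tok[4L])
      } else {
        cur$props[[tok[3L]]] <- list(list = FALSE, type = tok[2L])
      }
    } else if (tok[1L] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    } else {
      stop("malformed PLY header at line ", lineno, ": '", trimws(line), "'")
    }
  }
  if (is.null(format)) stop("malformed PLY header: no format line")
  if (is.null(elements$vertex)) stop("PLY file declares no vertex element")
  ascii <- format == "ascii"
  endian <- if (format == "binary_big_endian") "big" else "little"
  dialect <- switch(format,
    ascii = "ply_ascii",
    binary_little_endian = "ply_binary_le",
    binary_big_endian = "ply_binary_be",
    stop("unsupported PLY format: ", format)
  )
  if (ascii) {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    pos <- 0L
    out <- list()
    for (el in elements) {
      if (pos + el$count > length(body)) {
        stop(sprintf(
          "PLY declares %d '%s' records but only %d data lines remain",
          el$count, el$name, length(body) - pos
        ))
      }
      lines <- body[pos + seq_len(el$count)]
      pos <- pos + el$count
      out[[el$name]] <- lines
    }
    vprops <- names(elements$vertex$props)
    vtok <- strsplit(trimws(out$vertex), "\\s+")
    nv <- vapply(vtok, length, 1L)
    if (any(nv < length(vprops))) {
      stop("PLY vertex record with too few values at data line ", which(nv < length(vprops))[1L])
    }
    vm <- matrix(as.numeric(unlist(lapply(vtok, `[`, seq_along(vprops)))),
      ncol = length(vprops), byrow = TRUE
    )
    colnames(vm) <- vprops
    if (!all(c("x", "y", "z") %in% vprops)) stop("PLY vertex element lacks x/y/z properties")
    verts <- vm[, c("x", "y", "z"), drop = FALSE]
    fmat <- matrix(integer(0), 0L, 3L)
    if (!is.null(out$face) && elements$face$count > 0L) {
      ftok <- strsplit(trimws(out$face), "\\s+")
      counts <- vapply(ftok, function(t) as.integer(t[1L]), 1L)
      if (any(counts != 3L)) {
        stop("non-triangular face (", counts[which(counts != 3L)[1L]],
          " vertices); triangulate the mesh upstream")
      }
      fmat <- matrix(as.integer(unlist(lapply(ftok, `[`, 2:4))), ncol = 3L, byrow = TRUE) + 1L
    }
  } else {
    out <- list()
    for (el in elements) {
      props <- el$props
      if (el$name == "vertex") {
        types <- vapply(props, function(p) p$type, "")
        if (any(vapply(props, function(p) p$list, TRUE))) {
          stop("list properties on the vertex element are not supported")
        }
        if (length(unique(types)) == 1L) {
          vals <- .plyReadScalar(con, types[1L], el$count * length(props), endian)
          if (length(vals) < el$count * length(props)) {
            stop("PLY declares ", el$count, " vertices but the file is truncated")
          }
          vm <- matrix(vals, ncol = length(props), byrow = TRUE)
        } else {
          vm <- matrix(0, el$count, length(props))
          for (i in seq_len(el$count)) {
            for (j in seq_along(props)) {
              v <- .plyReadScalar(con, types[j], 1L, endian)
              if (length(v) < 1L) stop("PLY vertex data truncated at vertex ", i)
              vm[i, j] <- v
            }
          }
        }
        colnames(vm) <- names(props)
        out$vertex <- vm
      } else if (el$name == "face") {
        lp <- props[[1L]]
        if (length(props) != 1L || !lp$list) stop("unsupported face element layout")
        fmat0 <- matrix(0L, el$count, 3L)
        for (i in seq_len(el$count)) {
          cnt <- .plyReadScalar(con, lp$countType, 1L, endian)
          if (length(cnt) < 1L) stop("PLY declares ", el$count, " faces but the file is truncated")
          if (cnt != 3L) stop("non-triangular face (", cnt, " vertices); triangulate the mesh upstream")
          idx <- .plyReadScalar(con, lp$itemType, 3L, endian)
          if (length(idx) < 3L) stop("PLY face data truncated at face ", i)
          fmat0[i, ] <- idx
        }
        out$face <- fmat0 + 1L
      } else {
        # skip unknown fixed-size elements
        sizes <- vapply(el$props, function(p) {
          if (p$list) stop("cannot skip binary element '", el$name, "' with list properties")
          .plyTypeSize[[p$type]]
        }, 1L)
        invisible(readBin(con, "raw", n = el$count * sum(sizes)))
      }
    }
    vprops <- colnames(out$vertex)
    if (!all(c("x", "y", "z") %in% vprops)) stop("PLY vertex element lacks x/y/z properties")
    verts <- out$vertex[, c("x", "y", "z"), drop = FALSE]
    fmat <- if (is.null(out$face)) matrix(integer(0), 0L, 3L) else out$face
  }
  TriMesh(verts, fmat, dialect = dialect)
}

.writePLYascii <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  v <- mesh@vertices
  f <- mesh@faces
  header <- c(
    "ply", "format ascii 1.0",
    "comment written by semiland",
    sprintf("element vertex %d", nrow(v)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  )
  writeLines(header, con)
  writeLines(sprintf("%.17g %.17g %.17g", v[, 1L], v[, 2L], v[, 3L]), con)
  if (nrow(f) > 0L) {
    writeLines(sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L), con)
  }
}

.writePLYbinary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  v <- mesh@vertices
  f <- mesh@faces
  header <- c(
    "ply", "format binary_little_endian 1.0",
    "comment written by semiland",
    sprintf("element vertex %d", nrow(v)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  )
  writeLines(header, con)
  writeBin(as.vector(t(v)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(f))) {
    writeBin(3L, con, size = 1L, endian = "little")
    writeBin(as.integer(f[i, ] - 1L), con, size = 4L, endian = "little")
  }
}

## ---- STL ----

.readSTL <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  head_raw <- raw[seq_len(min(200L, length(raw)))]
  txt_head <- rawToChar(head_raw[head_raw != as.raw(0L)])
  is_ascii <- grepl("^\\s*solid", txt_head, useBytes = TRUE) &&
    grepl("facet", rawToChar(raw[raw != as.raw(0L)]), fixed = TRUE, useBytes = TRUE)
  if (is_ascii) {
    tok <- strsplit(rawToChar(raw), "\\s+")[[1L]]
    vi <- which(tok == "vertex")
    if (length(vi) %% 3L != 0L) stop("malformed ASCII STL: vertex count not a multiple of 3")
    tri <- matrix(as.numeric(tok[rep(vi, each = 3L) + 1:3]), ncol = 3L, byrow = TRUE)
    dialect <- "stl_ascii"
  } else {
    con <- rawConnection(raw)
    on.exit(close(con))
    invisible(readBin(con, "raw", n = 80L))
    nf <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    tri <- matrix(0, nf * 3L, 3L)
    for (i in seq_len(nf)) {
      vals <- readBin(con, "double", 12L, size = 4L, endian = "little")
      if (length(vals) < 12L) stop("binary STL truncated at facet ", i)
      invisible(readBin(con, "raw", n = 2L))
      tri[(i - 1L) * 3L + 1:3, ] <- matrix(vals[4:12], 3L, byrow = TRUE)
    }
    dialect <- "stl_binary"
  }
  weld <- .weldVertices(tri)
  faces <- matrix(weld$index, ncol = 3L, byrow = TRUE)
  keep <- faces[, 1L] != faces[, 2L] & faces[, 2L] != faces[, 3L] & faces[, 1L] != faces[, 3L]
  TriMesh(weld$vertices, faces[keep, , drop = FALSE], dialect = dialect)
}

# Weld coincident vertices within 1e-8 x bounding-box diagonal (grid hashing).
.weldVertices <- function(pts) {
  tol <- 1e-8 * max(.bboxDiagonal(pts), .Machine$double.eps)
  key <- paste(round(pts[, 1L] / tol), round(pts[, 2L] / tol), round(pts[, 3L] / tol))
  first <- !duplicated(key)
  index <- match(key, key[first])
  list(vertices = pts[first, , drop = FALSE], index = index)
}

.writeSTLbinary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  f <- mesh@faces
  v <- mesh@vertices
  writeBin(raw(80L), con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  fn <- .faceNormals(v, f)
  for (i in seq_len(nrow(f))) {
    writeBin(c(fn[i, ], t(v[f[i, ], ])), con, size = 4L, endian = "little")
    writeBin(raw(2L), con)
  }
}
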