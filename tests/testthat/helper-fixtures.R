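# Shared small fixtures, built once per test run.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, builder(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

# Unit tetrahedron (closed, 4 faces)
fixTetrahedron <- function() {
  cached("tetra", function() {
    v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
    semiland::TriMesh(v, f)
  })
}

# Small pyramid fixture with fossa and surface grid (used by many tests)
fixPyramid <- function() {
  cached("pyramid", function() {
    semiland::makePyramid(
      fossa = list(center = c(0.5, 0.35), radius = 0.14),
      mesh_resolution = 1000L, surface_grid = c(4L, 5L)
    )
  })
}

# Plain pyramid without fossa, lower resolution
fixPlainPyramid <- function() {
  cached("plain_pyramid", function() {
    semiland::makePyramid(mesh_resolution = 700L)
  })
}

# Random non-degenerate point configuration
randomConfig <- function(k, scale = 1) {
  matrix(runif(3 * k, -scale, scale), k, 3)
}

# Random 3D rotation matrix
randomRotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
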