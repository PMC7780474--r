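# Deterministic pyramid fixtures: specimen meshes with optional circular
# fossae, full point configurations, and the 16-configuration negligible-hole
# experiment.

# Barycentric grid triangulation of a triangle (A, B, C) with g subdivisions.
.triangulateTriangle <- function(A, B, C, g) {
  verts <- list()
  idx <- matrix(0L, g + 1L, g + 1L)
  cnt <- 0L
  for (i in 0:g) {
    for (j in 0:(g - i)) {
      cnt <- cnt + 1L
      verts[[cnt]] <- A + (i / g) * (B - A) + (j / g) * (C - A)
      idx[i + 1L, j + 1L] <- cnt
    }
  }
  faces <- list()
  fc <- 0L
  for (i in 0:(g - 1L)) {
    for (j in 0:(g - 1L - i)) {
      fc <- fc + 1L
      faces[[fc]] <- c(idx[i + 1L, j + 1L], idx[i + 2L, j + 1L], idx[i + 1L, j + 2L])
      if (j < g - 1L - i) {
        fc <- fc + 1L
        faces[[fc]] <- c(idx[i + 2L, j + 1L], idx[i + 2L, j + 2L], idx[i + 1L, j + 2L])
      }
    }
  }
  list(
    vertices = do.call(rbind, verts),
    faces = do.call(rbind, faces)
  )
}

# Position on the front lateral face (c1, c2, apex) from face coordinates:
# t across the base edge, s toward the apex.
.pyramidFacePoint <- function(corners, apex, t, s) {
  base <- corners[1L, ] + t * (corners[2L, ] - corners[1L, ])
  (1 - s) * base + s * apex
}

#' Generate a pyramidal specimen fixture
#'
#' Builds a watertight five-vertex pyramid (quadrilateral base, one apex) at a
#' target triangle count, with landmarks at every vertex and curves along
#' every edge — the geometry used to validate the negligible-hole patching
#' procedure. A circular fossa (a shallow spherical-cap depression, depth
#' 0.3 x radius, fenced by a closed curve) can be placed on the front lateral
#' face; alternatively a negligibly sized hole (same fence labels, minuscule
#' diameter, no depression) marks specimens lacking the fossa. A rows x cols
#' grid of surface points on the front face turns the fixture into a template.
#'
#' @param base_width,base_depth,height pyramid dimensions (mesh units).
#' @param corner_skew lateral shift of the back base edge (shears the base).
#' @param fossa `NULL` or `list(center = c(t, s), radius)` in front-face
#'   coordinates (t across the base edge, s toward the apex).
#' @param hole `NULL` or `list(center = c(t, s), spacing)`; fence diameter
#'   equals `spacing`.
#' @param mesh_resolution target face count.
#' @param curve_points points per edge curve after resampling (endpoints
#'   included).
#' @param fence_points fence curve points (anchor excluded).
#' @param surface_grid `NULL` or `c(rows, cols)` of template surface points on
#'   the front face.
#' @param specimen_id identifier.
#' @return list with `mesh` ([TriMesh-class]), `config`
#'   ([LandmarkConfig-class]) and `curves` (definition table).
#' @export
makePyramid <- function(base_width = 1, base_depth = 1, height = 1,
                        corner_skew = 0, fossa = NULL, hole = NULL,
                        mesh_resolution = 3000L, curve_points = 6L,
                        fence_points = 23L, surface_grid = NULL,
                        specimen_id = "pyramid") {
  stopifnot(base_width > 0, base_depth > 0, height > 0)
  c1 <- c(0, 0, 0)
  c2 <- c(base_width, 0, 0)
  c3 <- c(base_width + corner_skew, base_depth, 0)
  c4 <- c(corner_skew, base_depth, 0)
  apex <- c((base_width + corner_skew) / 2, base_depth / 2, height)
  g <- max(6L, as.integer(round(sqrt(mesh_resolution / 6))))
  pieces <- list(
    .triangulateTriangle(c1, c2, apex, g), # front (face 1)
    .triangulateTriangle(c2, c3, apex, g),
    .triangulateTriangle(c3, c4, apex, g),
    .triangulateTriangle(c4, c1, apex, g),
    .triangulateTriangle(c1, c3, c2, g), # base
    .triangulateTriangle(c1, c4, c3, g)
  )
  off <- 0L
  V <- list()
  F_ <- list()
  for (p in pieces) {
    V[[length(V) + 1L]] <- p$vertices
    F_[[length(F_) + 1L]] <- p$faces + off
    off <- off + nrow(p$vertices)
  }
  V <- do.call(rbind, V)
  F_ <- do.call(rbind, F_)
  weld <- .weldVertices(V)
  V <- weld$vertices
  F_ <- matrix(weld$index[F_], ncol = 3L)
  keep <- F_[, 1L] != F_[, 2L] & F_[, 2L] != F_[, 3L] & F_[, 1L] != F_[, 3L]
  F_ <- F_[keep, , drop = FALSE]
  corners <- rbind(c1, c2)
  fossaCenter3d <- NULL
  if (!is.null(fossa)) {
    ctr <- .pyramidFacePoint(corners, apex, fossa$center[1L], fossa$center[2L])
    fossaCenter3d <- ctr
    # guard: the fence must stay inside the front face
    e1 <- c2 - c1
    fn <- .faceNormals(rbind(c1, c2, apex), matrix(1:3, 1L))[1L, ]
    rim <- vapply(seq(0, 2 * pi, length.out = 13L), function(th) {
      p <- ctr + fossa$radius * (cos(th) * (e1 / sqrt(sum(e1^2))) +
        sin(th) * .unitCross(fn, e1))
      .pointTriangleMargin(p, c1, c2, apex)
    }, 1)
    if (any(rim < 0)) stop("fossa exceeds the front face")
    # spherical-cap depression along the inward face normal
    depth <- 0.3 * fossa$radius
    d2ctr <- sqrt(colSums((t(V) - ctr)^2))
    inside <- d2ctr < fossa$radius
    disp <- depth * (1 - (d2ctr[inside] / fossa$radius)^2)
    V[inside, ] <- V[inside, , drop = FALSE] - outer(disp, fn)
  }
  mesh <- TriMesh(V, F_, fixWinding = TRUE)
  # landmarks at the five vertices, curves along the eight edges
  lm <- rbind(apex = apex, base_fl = c1, base_fr = c2, base_br = c3, base_bl = c4)
  edges <- list(
    edge_front = c("base_fl", "base_fr"), edge_right = c("base_fr", "base_br"),
    edge_back = c("base_br", "base_bl"), edge_left = c("base_bl", "base_fl"),
    rise_fl = c("base_fl", "apex"), rise_fr = c("base_fr", "apex"),
    rise_br = c("base_br", "apex"), rise_bl = c("base_bl", "apex")
  )
  pts <- data.frame(
    label = rownames(lm), class = "landmark", region = "face1",
    curve_id = NA_character_, ordinal = NA_integer_, side = "none",
    stringsAsFactors = FALSE
  )
  xyz <- lm
  curves <- do.call(rbind, lapply(names(edges), function(e) {
    curveDefinition(e, edges[[e]][1L], edges[[e]][2L], curve_points)
  }))
  for (e in names(edges)) {
    seg <- rbind(lm[edges[[e]][1L], ], lm[edges[[e]][2L], ])
    rs <- resampleCurve(seg, curve_points)
    inner <- rs[-c(1L, nrow(rs)), , drop = FALSE]
    ni <- nrow(inner)
    pts <- rbind(pts, data.frame(
      label = sprintf("%s_%02d", e, seq_len(ni)), class = "curve",
      region = "face1", curve_id = e, ordinal = seq_len(ni) - 1L,
      side = "none", stringsAsFactors = FALSE
    ))
    xyz <- rbind(xyz, inner)
  }
  # fence: around the fossa, or a negligibly sized hole
  fence <- NULL
  if (!is.null(fossa)) {
    fence <- makeNegligibleHole(mesh, fossaCenter3d, 2 * fossa$radius,
      curve_id = "fence", anchor_label = "fence_anchor",
      n_points = fence_points, region = "face1"
    )
  } else if (!is.null(hole)) {
    ctr <- .pyramidFacePoint(corners, apex, hole$center[1L], hole$center[2L])
    fence <- makeNegligibleHole(mesh, ctr, hole$spacing,
      curve_id = "fence", anchor_label = "fence_anchor",
      n_points = fence_points, region = "face1"
    )
  }
  if (!is.null(fence)) {
    pts <- rbind(pts, fence$fragment@points)
    xyz <- rbind(xyz, fence$fragment@coords)
    curves <- rbind(curves, fence$curve)
  }
  if (!is.null(surface_grid)) {
    rows <- surface_grid[1L]
    cols <- surface_grid[2L]
    sp <- list()
    for (i in seq_len(rows)) {
      for (j in seq_len(cols)) {
        sp[[length(sp) + 1L]] <- .pyramidFacePoint(
          corners, apex, j / (cols + 1L), i / (rows + 1L)
        )
      }
    }
    sp <- do.call(rbind, sp)
    sp <- nearestPointOnMesh(mesh, sp)$point
    ns <- nrow(sp)
    pts <- rbind(pts, data.frame(
      label = sprintf("surf_%03d", seq_len(ns)), class = "surface",
      region = "face1", curve_id = NA_character_, ordinal = NA_integer_,
      side = "none", stringsAsFactors = FALSE
    ))
    xyz <- rbind(xyz, sp)
  }
  config <- LandmarkConfig(specimen_id, pts, xyz)
  validObject(config)
  list(mesh = mesh, config = config, curves = curves)
}

.unitCross <- function(a, b) {
  v <- c(
    a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L]
  )
  v / sqrt(sum(v^2))
}

# Signed margin of p inside triangle (A,B,C): minimum distance to the three
# edges, positive inside (computed in the triangle plane).
.pointTriangleMargin <- function(p, A, B, C) {
  n <- .unitCross(B - A, C - A)
  edgeDist <- function(E1, E2, opp) {
    d <- E2 - E1
    inward <- .unitCross(n, d)
    if (sum(inward * (opp - E1)) < 0) inward <- -inward
    sum(inward * (p - E1))
  }
  min(edgeDist(A, B, C), edgeDist(B, C, A), edgeDist(C, A, B))
}

#' Generate the 16-configuration negligible-hole pyramid experiment
#'
#' Ten pyramids of seeded varying proportions (base aspect 0.6-1.6,
#' height 0.5-2.0, corner skew), four of which carry a circular fossa on the
#' front face; one template pyramid with 90 surface points (a 9 x 10 grid) on
#' that face; negligible-hole fences for the six no-fossa specimens, plus the
#' same six specimens prepared again with all fence labels removed (the
#' re-patch without a hole). Patching the 10 + 6 preparations yields the 16
#' configurations compared in a common alignment.
#'
#' @param seed integer seed for the proportion draws.
#' @param mesh_resolution face-count target for specimen meshes.
#' @param template_resolution face-count target for the template mesh.
#' @param curve_points points per edge curve (endpoints included).
#' @return list with `template` (an [Atlas-class]), `template_nohole` (fence
#'   labels dropped), `specimens` (list of `mesh`/`config`/`curves`/`fossa`),
#'   and `manifest` (all drawn parameters).
#' @export
makePyramidExperiment <- function(seed = 1L, mesh_resolution = 2400L,
                                  template_resolution = 3500L,
                                  curve_points = 6L) {
  set.seed(seed)
  n <- 10L
  params <- data.frame(
    specimen = sprintf("pyr%02d", seq_len(n)),
    base_depth = runif(n, 0.6, 1.6),
    height = runif(n, 0.5, 2.0),
    corner_skew = runif(n, -0.2, 0.2),
    fossa_radius = c(runif(4L, 0.10, 0.16), rep(NA_real_, 6L)),
    has_fossa = c(rep(TRUE, 4L), rep(FALSE, 6L))
  )
  faceCenter <- c(0.5, 0.35)
  holeSpacing <- 1 / 11 # about one surface-point spacing on the 9 x 10 grid
  template <- makePyramid(
    base_width = 1, base_depth = 1, height = 1, corner_skew = 0,
    hole = list(center = faceCenter, spacing = holeSpacing),
    mesh_resolution = template_resolution, curve_points = curve_points,
    surface_grid = c(9L, 10L), specimen_id = "template"
  )
  atlas <- suppressWarnings(
    buildAtlas(template$mesh, template$config, template$curves, min_faces = 0L)
  )
  fenceLabels <- template$config@points$label[
    template$config@points$curve_id %in% "fence" |
      template$config@points$label == "fence_anchor"
  ]
  cfgNoHole <- dropPoints(template$config, fenceLabels)
  atlasNoHole <- suppressWarnings(buildAtlas(
    template$mesh, cfgNoHole,
    template$curves[template$curves$curve_id != "fence", , drop = FALSE],
    min_faces = 0L
  ))
  specimens <- vector("list", n)
  for (i in seq_len(n)) {
    p <- params[i, ]
    specimens[[i]] <- makePyramid(
      base_width = 1, base_depth = p$base_depth, height = p$height,
      corner_skew = p$corner_skew,
      fossa = if (p$has_fossa) list(center = faceCenter, radius = p$fossa_radius),
      hole = if (!p$has_fossa) list(center = faceCenter, spacing = holeSpacing),
      mesh_resolution = mesh_resolution, curve_points = curve_points,
      specimen_id = p$specimen
    )
    specimens[[i]]$fossa <- p$has_fossa
  }
  names(specimens) <- params$specimen
  list(
    template = atlas, template_nohole = atlasNoHole, specimens = specimens,
    fence_labels = fenceLabels,
    manifest = list(
      seed = seed, params = params, face_center = faceCenter,
      hole_spacing = holeSpacing, mesh_resolution = mesh_resolution,
      template_resolution = template_resolution, curve_points = curve_points,
      surface_grid = c(9L, 10L)
    )
  )
}

#' Run the negligible-hole pyramid experiment end to end
#'
#' Patches the ten pyramids through the shared template (negligible-hole
#' fences on the six no-fossa specimens), re-patches those six without any
#' fence, removes the non-comparable fence labels from every configuration,
#' and subjects all 16 configurations to a common Procrustes alignment and
#' PCA.
#'
#' @param seed integer seed passed to [makePyramidExperiment()].
#' @param inflate inflate value for patching (front faces are flat to
#'   concave, so the working value is 0).
#' @param ... further arguments to [makePyramidExperiment()].
#' @return list with `alignment` (an [AlignmentResult-class] over the 16
#'   configurations), `configs`, `pairs` (two-column matrix of the six
#'   with/without-hole twin ids), `cumvar4` (cumulative percent variance of
#'   PC1-PC4) and `bundle`.
#' @export
runPyramidExperiment <- function(seed = 1L, inflate = 0, ...) {
  bundle <- makePyramidExperiment(seed, ...)
  configs <- list()
  for (nm in names(bundle$specimens)) {
    sp <- bundle$specimens[[nm]]
    res <- placePatch(bundle$template, sp$mesh, sp$config, inflate = inflate)
    if (res@failed) stop("patching failed for ", nm, ": ", res@reason)
    configs[[nm]] <- dropPoints(res@config, bundle$fence_labels)
  }
  for (nm in names(bundle$specimens)) {
    sp <- bundle$specimens[[nm]]
    if (sp$fossa) next
    fixedNoHole <- dropPoints(sp$config, bundle$fence_labels)
    fixedNoHole@specimenId <- paste0(nm, "_nf")
    res <- placePatch(bundle$template_nohole, sp$mesh, fixedNoHole, inflate = inflate)
    if (res@failed) stop("patching failed for ", nm, "_nf: ", res@reason)
    configs[[paste0(nm, "_nf")]] <- res@config
  }
  alignment <- gpa(configs)
  ev <- alignment@pca$values
  cumvar4 <- 100 * sum(ev[seq_len(min(4L, length(ev)))]) / sum(ev)
  twins <- names(bundle$specimens)[!vapply(bundle$specimens, `[[`, TRUE, "fossa")]
  pairs <- cbind(twins, paste0(twins, "_nf"))
  list(
    alignment = alignment, configs = configs, pairs = pairs,
    cumvar4 = cumvar4, bundle = bundle
  )
}
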