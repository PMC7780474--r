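#' Bind a template mesh to its point configuration
#'
#' Validates that every template point sits on the template surface and that
#' fixed-point labels are unique, then packages mesh, configuration, curve
#' definitions and the region map of surface points. Template resolution
#' matters because the mesh is warped to each specimen: meshes below ~10,000
#' faces deform too coarsely for skull-scale work, so a warning is issued
#' (about 18,000 faces is a proven default for vertebrate crania).
#'
#' @param mesh template [TriMesh-class].
#' @param config template [LandmarkConfig-class] (landmarks, resampled curve
#'   points, surface points).
#' @param curves curve definition data.frame (see [curveDefinition()]).
#' @param tol on-surface tolerance as a fraction of the template bounding-box
#'   diagonal.
#' @param min_faces resolution below which a warning is issued.
#' @return An [Atlas-class].
#' @export
buildAtlas <- function(mesh, config, curves, tol = 1e-3, min_faces = 10000L) {
  validObject(config)
  np <- nearestPointOnMesh(mesh, config@coords)
  bad <- which(np$distance > tol * .bboxDiagonal(mesh@vertices))
  if (length(bad)) {
    stop(
      "template points off the template surface: ",
      paste(config@points$label[bad], collapse = ", ")
    )
  }
  if (nFaces(mesh) < min_faces) {
    warning(sprintf(
      "template mesh has only %d faces; meshes this coarse may deform poorly (~18,000 faces is a proven default)",
      nFaces(mesh)
    ))
  }
  surf <- config@points[config@points$class == "surface", , drop = FALSE]
  regionMap <- split(surf$label, surf$region)
  new("Atlas", mesh = mesh, config = config, curves = curves, regionMap = regionMap)
}

# Fixed (landmark + curve) labels of an atlas, in canonical order.
.atlasFixedLabels <- function(atlas) {
  pts <- atlas@config@points
  pts$label[pts$class != "surface"]
}

#' Project template surface points onto a specimen (patching)
#'
#' The semi-automated transfer of surface semilandmarks: (1) fit a TPS from
#' the atlas fixed points (landmarks + curve points) to the specimen's fixed
#' points; (2) warp the atlas surface points and the atlas mesh, producing the
#' intermediate model; (3) displace each warped surface point outward by
#' `inflate` along the warped template normal (inflation prevents capture by
#' internal surfaces; too much inflation lets points jump onto nearby
#' external surfaces); (4) deflate: cast a ray back along the negative normal
#' and take the first contact with the specimen mesh, falling back to the
#' positive normal and then to the globally nearest surface point;
#' (5) optionally relax the placed points toward the atlas configuration by
#' tangent-plane bending-energy sliding and re-project.
#'
#' Failure (fixed points floating off the specimen surface — the leading
#' practical cause) is reported as a value (`failed = TRUE`), not an
#' exception, so batch runs complete and report.
#'
#' @param atlas an [Atlas-class].
#' @param specimen_mesh specimen [TriMesh-class].
#' @param specimen_fixed [LandmarkConfig-class] containing exactly the atlas's
#'   fixed labels, with curve points already resampled and on the specimen
#'   surface.
#' @param inflate scalar displacement along normals before back-projection.
#'   With `inflate_mode = "absolute"` it is in mesh units (specimen-dependent);
#'   `"relative"` scales it by the specimen fixed configuration's centroid
#'   size, which travels better across differently sized specimens.
#' @param relax_to_atlas logical; relax placed surface points toward the atlas
#'   (increases failure rates on hard specimens, hence default `FALSE`).
#' @param stepsize damping for the optional relaxation.
#' @param inflate_mode `"absolute"` or `"relative"`.
#' @param tol floating-point tolerance for fixed points, as a fraction of the
#'   specimen bounding-box diagonal.
#' @param off_region_factor multiple of the median warped surface-point
#'   spacing beyond which a projection jump is flagged off-region.
#' @return A [PatchResult-class].
#' @export
placePatch <- function(atlas, specimen_mesh, specimen_fixed, inflate = 0,
                       relax_to_atlas = FALSE, stepsize = 0.1,
                       inflate_mode = c("absolute", "relative"),
                       tol = 1e-3, off_region_factor = 3) {
  inflate_mode <- match.arg(inflate_mode)
  fixedLabels <- .atlasFixedLabels(atlas)
  specLabels <- specimen_fixed@points$label
  if (!setequal(fixedLabels, specLabels)) {
    miss <- setdiff(fixedLabels, specLabels)
    extra <- setdiff(specLabels, fixedLabels)
    stop(sprintf(
      "fixed-point labels do not match the atlas: missing {%s}, extra {%s}",
      paste(miss, collapse = ","), paste(extra, collapse = ",")
    ))
  }
  atlasPts <- atlas@config@points
  surfSel <- atlasPts$class == "surface"
  atlasFixedXYZ <- atlas@config@coords[!surfSel, , drop = FALSE]
  atlasSurfXYZ <- atlas@config@coords[surfSel, , drop = FALSE]
  specFixedXYZ <- specimen_fixed@coords[fixedLabels, , drop = FALSE]
  # floating fixed points => recoverable failure
  diag0 <- .bboxDiagonal(specimen_mesh@vertices)
  npFixed <- nearestPointOnMesh(specimen_mesh, specFixedXYZ)
  floating <- which(npFixed$distance > tol * diag0)
  emptyDiag <- data.frame(
    label = character(0), distance = numeric(0), normalAgreement = numeric(0),
    method = character(0), offRegion = logical(0), stringsAsFactors = FALSE
  )
  if (length(floating)) {
    return(new("PatchResult",
      config = specimen_fixed, diagnostics = emptyDiag, failed = TRUE,
      reason = paste0(
        "floating fixed points (off the specimen surface): ",
        paste(fixedLabels[floating], collapse = ", ")
      )
    ))
  }
  model <- fitTPS(atlasFixedXYZ, specFixedXYZ)
  warpedSurf <- warpPoints(model, atlasSurfXYZ)
  warpedTemplate <- warpMesh(model, atlas@mesh)
  npWarp <- nearestPointOnMesh(warpedTemplate, warpedSurf)
  fnWarp <- .faceNormals(warpedTemplate@vertices, warpedTemplate@faces)
  normals <- fnWarp[npWarp$face, , drop = FALSE]
  inflateAbs <- if (inflate_mode == "relative") {
    inflate * centroidSize(specFixedXYZ)
  } else {
    inflate
  }
  inflated <- warpedSurf + inflateAbs * normals
  nSurf <- nrow(inflated)
  placed <- matrix(NA_real_, nSurf, 3L)
  method <- character(nSurf)
  agree <- numeric(nSurf)
  fnSpec <- .faceNormals(specimen_mesh@vertices, specimen_mesh@faces)
  for (j in seq_len(nSurf)) {
    hitFound <- FALSE
    for (sense in c(-1, 1)) {
      d <- sense * normals[j, ]
      h <- cpp_ray_hits(specimen_mesh@vertices, specimen_mesh@faces, inflated[j, ], d)
      fwd <- which(h$t > -1e-9 * diag0)
      if (length(fwd)) {
        best <- fwd[which.min(h$t[fwd])]
        placed[j, ] <- h$point[best, ]
        # agreement: hit face normal vs the outward template normal
        agree[j] <- sign(h$normal_dot[best] * sense)
        method[j] <- if (sense == -1) "ray_neg" else "ray_pos"
        hitFound <- TRUE
        break
      }
    }
    if (!hitFound) {
      np1 <- nearestPointOnMesh(specimen_mesh, inflated[j, ])
      placed[j, ] <- np1$point
      agree[j] <- sign(sum(fnSpec[np1$face, ] * normals[j, ]))
      method[j] <- "nearest"
    }
  }
  # off-region proxy: projection jumped much farther than the local point
  # spacing on the warped template
  jump <- sqrt(rowSums((placed - warpedSurf)^2))
  spacing <- if (nSurf > 1L) {
    dd <- .crossDist(warpedSurf, warpedSurf)
    diag(dd) <- Inf
    median(apply(dd, 1L, min))
  } else {
    Inf
  }
  offRegion <- jump > off_region_factor * spacing + abs(inflateAbs)
  surfLabels <- atlasPts$label[surfSel]
  # assemble in the atlas's canonical order
  outXYZ <- matrix(NA_real_, nrow(atlasPts), 3L)
  outXYZ[!surfSel, ] <- specFixedXYZ
  outXYZ[surfSel, ] <- placed
  outPts <- atlasPts
  config <- LandmarkConfig(specimen_fixed@specimenId, outPts, outXYZ)
  if (relax_to_atlas) {
    relaxed <- slideSemilandmarks(
      configs = stats::setNames(list(config), specimen_fixed@specimenId),
      meshes = list(specimen_mesh), curves = atlas@curves,
      spec = slidingSpec(
        criterion = "bending_energy", stepsize = stepsize,
        max_iterations = 5L, reference_mode = "fixed_reference",
        slide_curves = FALSE, slide_surfaces = TRUE
      ),
      reference = atlas@config@coords
    )
    config <- relaxed$configs[[1L]]
    placed <- config@coords[surfLabels, , drop = FALSE]
  }
  npFinal <- nearestPointOnMesh(specimen_mesh, placed)
  diagn <- data.frame(
    label = surfLabels, distance = npFinal$distance, normalAgreement = agree,
    method = method, offRegion = offRegion, stringsAsFactors = FALSE
  )
  new("PatchResult", config = config, diagnostics = diagn, failed = FALSE, reason = "")
}

#' Patch a specimen region by region and merge
#'
#' Runs [placePatch()] per region and merges the placements into a single
#' configuration in canonical order. Patching small regions in isolation can
#' place points on the reverse side of the mesh polygons (face inversion); the
#' documented remedy is to include a neighbouring region's fixed points as
#' additional warp anchors without patching that region, which
#' `anchor_regions` implements.
#'
#' @param atlas_per_region named list region -> [Atlas-class]. Each atlas may
#'   carry the full fixed configuration; the fixed points used for a region
#'   are those whose `region` matches, plus any anchors.
#' @param specimen_mesh specimen [TriMesh-class].
#' @param specimen_fixed [LandmarkConfig-class] with all fixed points.
#' @param inflate_per_region named list/vector of per-region inflate values
#'   (a single value is recycled).
#' @param anchor_regions optional named list region -> extra fixed labels to
#'   include as TPS anchors for that region.
#' @param ... further arguments passed to [placePatch()].
#' @return A [PatchResult-class]; `failed` is `TRUE` when any region failed.
#' @export
piecemealPatch <- function(atlas_per_region, specimen_mesh, specimen_fixed,
                           inflate_per_region = 0, anchor_regions = list(), ...) {
  regions <- names(atlas_per_region)
  if (is.null(regions)) stop("atlas_per_region must be a named list")
  if (length(inflate_per_region) == 1L && is.null(names(inflate_per_region))) {
    inflate_per_region <- stats::setNames(
      rep(as.numeric(inflate_per_region), length(regions)), regions
    )
  }
  allSurfLabels <- unlist(lapply(atlas_per_region, function(a) {
    pts <- a@config@points
    pts$label[pts$class == "surface" & pts$region %in% regions]
  }))
  seen <- character(0)
  results <- list()
  for (r in regions) {
    atlas <- atlas_per_region[[r]]
    pts <- atlas@config@points
    keepFixed <- pts$class != "surface" &
      (pts$region == r | pts$label %in% anchor_regions[[r]])
    # keep whole curves so ordinals stay consecutive
    curveIds <- unique(pts$curve_id[keepFixed & pts$class == "curve"])
    keepFixed <- keepFixed | (pts$class == "curve" & pts$curve_id %in% curveIds)
    anchorLms <- unique(unlist(atlas@curves[atlas@curves$curve_id %in% curveIds,
      c("start_landmark", "end_landmark")
    ]))
    keepFixed <- keepFixed | pts$label %in% anchorLms
    keepSurf <- pts$class == "surface" & pts$region == r
    if (any(pts$label[keepSurf] %in% seen)) {
      stop("overlapping surface-point labels across regions")
    }
    seen <- c(seen, pts$label[keepSurf])
    keep <- keepFixed | keepSurf
    subConfig <- LandmarkConfig(
      atlas@config@specimenId, pts[keep, , drop = FALSE],
      atlas@config@coords[keep, , drop = FALSE]
    )
    subCurves <- atlas@curves[atlas@curves$curve_id %in%
      unique(pts$curve_id[keep & pts$class == "curve"]), , drop = FALSE]
    subAtlas <- suppressWarnings(buildAtlas(atlas@mesh, subConfig, subCurves,
      min_faces = 0L
    ))
    subFixedLabels <- .atlasFixedLabels(subAtlas)
    specSub <- dropPoints(
      specimen_fixed,
      function(p) !(p$label %in% subFixedLabels)
    )
    res <- placePatch(subAtlas, specimen_mesh, specSub,
      inflate = inflate_per_region[[r]], ...
    )
    if (res@failed) {
      return(new("PatchResult",
        config = specimen_fixed, diagnostics = res@diagnostics, failed = TRUE,
        reason = sprintf("region '%s': %s", r, res@reason)
      ))
    }
    results[[r]] <- res
  }
  # merge: all fixed points in specimen order, then surface placements in
  # canonical (atlas) order per region
  mergedPts <- specimen_fixed@points
  mergedXYZ <- specimen_fixed@coords
  diagn <- list()
  for (r in regions) {
    res <- results[[r]]
    sel <- res@config@points$class == "surface"
    mergedPts <- rbind(mergedPts, res@config@points[sel, , drop = FALSE])
    mergedXYZ <- rbind(mergedXYZ, res@config@coords[sel, , drop = FALSE])
    diagn[[r]] <- res@diagnostics
  }
  config <- LandmarkConfig(specimen_fixed@specimenId, mergedPts, mergedXYZ)
  new("PatchResult",
    config = config, diagnostics = do.call(rbind, c(diagn, list(make.row.names = FALSE))),
    failed = FALSE, reason = ""
  )
}
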