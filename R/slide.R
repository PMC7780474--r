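#' Sliding specification
#'
#' Bundle of parameters controlling semilandmark sliding. The default
#' criterion is bending energy; Procrustes distance is offered because the
#' two give near-identical results for high-variation samples. The default
#' stepsize of 0.1 damps tangent displacements: large steps let curve points
#' leave their defining curves between re-projections.
#'
#' @param criterion `"bending_energy"` or `"procrustes_distance"`.
#' @param stepsize damping factor in [0, 1] applied to curve-point
#'   displacements per outer iteration (0 disables sliding).
#' @param surface_stepsize damping for surface points (defaults to
#'   `stepsize`).
#' @param max_iterations outer iteration cap.
#' @param tolerance relative change in mean Procrustes distance to the
#'   reference below which iteration stops.
#' @param reference_mode `"sample_mean"` (GPA mean recomputed each outer
#'   iteration) or `"fixed_reference"` (relax toward a supplied template).
#' @param slide_curves,slide_surfaces logical switches per point class.
#' @return list of class `slidingSpec`.
#' @export
slidingSpec <- function(criterion = c("bending_energy", "procrustes_distance"),
                        stepsize = 0.1, surface_stepsize = stepsize,
                        max_iterations = 50L, tolerance = 1e-6,
                        reference_mode = c("sample_mean", "fixed_reference"),
                        slide_curves = TRUE, slide_surfaces = TRUE) {
  stopifnot(
    stepsize >= 0, stepsize <= 1, surface_stepsize >= 0, surface_stepsize <= 1,
    max_iterations >= 1L, tolerance >= 0
  )
  structure(
    list(
      criterion = match.arg(criterion), stepsize = stepsize,
      surface_stepsize = surface_stepsize,
      max_iterations = as.integer(max_iterations), tolerance = tolerance,
      reference_mode = match.arg(reference_mode),
      slide_curves = slide_curves, slide_surfaces = slide_surfaces
    ),
    class = "slidingSpec"
  )
}

#' Per-point tangent structures for sliding
#'
#' Curve points receive a unit tangent along their curve (central difference
#' of their neighbours, anchors included; wrap-around for closed curves);
#' surface points receive an orthonormal tangent-plane pair from the mesh
#' normal at their nearest face; landmarks receive an empty basis and never
#' slide. Degenerate (zero-length) tangents demote the point to fixed with a
#' warning.
#'
#' @param config a [LandmarkConfig-class].
#' @param curves curve definition data.frame (see [curveDefinition()]).
#' @param mesh the specimen [TriMesh-class] (needed for surface points; may be
#'   `NULL` when the configuration has none).
#' @return list of length n: `NULL`, or a 3 x 1 / 3 x 2 orthonormal basis.
#' @export
tangentStructures <- function(config, curves, mesh = NULL) {
  pts <- config@points
  xyz <- config@coords
  n <- nrow(pts)
  out <- vector("list", n)
  for (ci in seq_len(nrow(curves))) {
    crv <- curves[ci, ]
    poly <- .curvePolyline(config, crv)
    rows <- poly$curveRows
    if (!length(rows)) next
    path <- poly$coords
    m <- nrow(path)
    for (j in seq_along(rows)) {
      pos <- j + 1L # position within path (anchor first)
      if (isTRUE(crv$closed)) {
        prev <- if (pos == 2L) path[m - 1L, ] else path[pos - 1L, ]
        nxt <- path[pos + 1L, ]
      } else {
        prev <- path[pos - 1L, ]
        nxt <- path[pos + 1L, ]
      }
      tangent <- nxt - prev
      len <- sqrt(sum(tangent^2))
      if (len < 1e-12) {
        warning("degenerate tangent at curve point ", pts$label[rows[j]], "; point treated as fixed")
        next
      }
      out[[rows[j]]] <- matrix(tangent / len, 3L, 1L)
    }
  }
  surf <- which(pts$class == "surface")
  if (length(surf)) {
    if (is.null(mesh)) stop("mesh required for surface-point tangent planes")
    np <- nearestPointOnMesh(mesh, xyz[surf, , drop = FALSE])
    fn <- .faceNormals(mesh@vertices, mesh@faces)
    for (j in seq_along(surf)) {
      nrm <- fn[np$face[j], ]
      a <- if (abs(nrm[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      t1 <- a - sum(a * nrm) * nrm
      t1 <- t1 / sqrt(sum(t1^2))
      t2 <- c(
        nrm[2L] * t1[3L] - nrm[3L] * t1[2L],
        nrm[3L] * t1[1L] - nrm[1L] * t1[3L],
        nrm[1L] * t1[2L] - nrm[2L] * t1[1L]
      )
      out[[surf[j]]] <- cbind(t1, t2)
    }
  }
  out
}

# Project points onto a polyline (closest point over all segments).
.projectToPolyline <- function(points, polyline) {
  points <- if (is.null(dim(points))) matrix(points, 1L, 3L) else as.matrix(points)
  a <- polyline[-nrow(polyline), , drop = FALSE]
  b <- polyline[-1L, , drop = FALSE]
  d <- b - a
  len2 <- rowSums(d^2)
  len2[len2 == 0] <- 1
  out <- points
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    tt <- (sweep(a, 2L, p, "-") * d)
    tt <- -rowSums(tt) / len2
    tt <- pmin(pmax(tt, 0), 1)
    cand <- a + d * tt
    d2 <- rowSums(sweep(cand, 2L, p)^2)
    out[i, ] <- cand[which.min(d2), ]
  }
  out
}

# Superimpose the reference shape into a specimen's own coordinate space
# (translation + scale + rotation fitting ref onto the specimen).
.referenceInSpecimenSpace <- function(reference, spec) {
  A <- sweep(spec, 2L, colMeans(spec))
  B <- sweep(reference, 2L, colMeans(reference))
  R <- .optimalRotation(A, B)
  BR <- B %*% R
  s <- sum(A * BR) / sum(BR^2)
  sweep(s * BR, 2L, colMeans(spec), "+")
}

# Solve the per-specimen tangent-restricted displacement.
.solveSlide <- function(Y, refSpec, tangents, slidable, criterion) {
  delta <- matrix(0, nrow(Y), 3L)
  if (!length(slidable)) return(delta)
  if (criterion == "procrustes_distance") {
    for (i in slidable) {
      D <- tangents[[i]]
      delta[i, ] <- D %*% crossprod(D, refSpec[i, ] - Y[i, ])
    }
    return(delta)
  }
  B <- bendingEnergyMatrix(refSpec)
  dofPoint <- integer(0)
  dofDir <- list()
  for (i in slidable) {
    D <- tangents[[i]]
    for (c_ in seq_len(ncol(D))) {
      dofPoint <- c(dofPoint, i)
      dofDir[[length(dofDir) + 1L]] <- D[, c_]
    }
  }
  m <- length(dofPoint)
  Dm <- matrix(unlist(dofDir), nrow = 3L) # 3 x m
  G <- crossprod(Dm) # m x m direction dot products
  M <- B[dofPoint, dofPoint, drop = FALSE] * G
  BY <- B %*% Y # k x 3
  rhs <- -colSums(Dm * t(BY[dofPoint, , drop = FALSE]))
  t_ <- tryCatch(solve(M, rhs), error = function(e) {
    lam <- 1e-8 * mean(diag(M)) + 1e-300
    message(sprintf("singular sliding system; ridge fallback with lambda = %.3g", lam))
    solve(M + diag(lam, m), rhs)
  })
  for (a in seq_len(m)) {
    delta[dofPoint[a], ] <- delta[dofPoint[a], ] + Dm[, a] * t_[a]
  }
  delta
}

#' Slide curve and surface semilandmarks across a sample
#'
#' Iterative sliding: (a) compute the reference shape (GPA mean, recomputed
#' each outer iteration, or a fixed template); (b) per specimen, superimpose
#' the reference into the specimen's space and solve for the tangent-plane /
#' tangent-line displacements minimizing the criterion (generalized least
#' squares for bending energy; orthogonal projection of the deviation for
#' Procrustes distance); (c) damp the displacement by the stepsize; (d)
#' re-project slid curve points onto their digitized polyline and surface
#' points onto the specimen mesh; repeat until the relative change in the
#' mean Procrustes distance to the reference falls below the tolerance.
#'
#' With stepsize 1 and before re-projection, the solved configuration's
#' criterion value never exceeds the pre-step value (exact minimization of a
#' PSD quadratic form restricted to the tangent subspace).
#'
#' @param configs named list of [LandmarkConfig-class] with a shared point
#'   order.
#' @param meshes named list of [TriMesh-class] matching `configs` (or a single
#'   mesh used for all specimens).
#' @param curves curve definition data.frame.
#' @param spec a [slidingSpec()].
#' @param reference optional k x 3 matrix or [LandmarkConfig-class]; required
#'   when `spec$reference_mode == "fixed_reference"`.
#' @return list with `configs` (slid configurations), and `trace` — a
#'   data.frame per outer iteration with the mean criterion value against the
#'   current reference before the step, the mean pre-projection deviation of
#'   curve points from their polylines, and the relative change used for the
#'   convergence test.
#' @export
slideSemilandmarks <- function(configs, meshes, curves, spec = slidingSpec(),
                               reference = NULL) {
  stopifnot(is.list(configs), length(configs) >= 1L)
  if (is(meshes, "TriMesh")) meshes <- rep(list(meshes), length(configs))
  stopifnot(length(meshes) == length(configs))
  n <- length(configs)
  pts <- configs[[1L]]@points
  fixedRef <- NULL
  if (spec$reference_mode == "fixed_reference") {
    if (is.null(reference)) stop("fixed_reference mode needs a reference")
    fixedRef <- if (is(reference, "LandmarkConfig")) reference@coords else as.matrix(reference)
  }
  # digitized polylines are frozen at input for re-projection
  polylines <- lapply(configs, function(cfg) {
    lapply(seq_len(nrow(curves)), function(ci) .curvePolyline(cfg, curves[ci, ]))
  })
  curveRows <- which(pts$class == "curve")
  surfRows <- which(pts$class == "surface")
  trace <- data.frame()
  lastDist <- NA_real_
  for (iter in seq_len(spec$max_iterations)) {
    ref <- if (is.null(fixedRef)) {
      if (n >= 2L) {
        res <- gpa(configs)
        res@meanShape
      } else {
        configs[[1L]]@coords
      }
    } else {
      fixedRef
    }
    critSum <- 0
    curveDev <- 0
    nCurvePts <- max(1L, length(curveRows) * n)
    newConfigs <- configs
    for (i in seq_len(n)) {
      Y <- configs[[i]]@coords
      refSpec <- .referenceInSpecimenSpace(ref, Y)
      critSum <- critSum + if (spec$criterion == "bending_energy") {
        bendingEnergy(refSpec, Y)
      } else {
        sum((refSpec - Y)^2)
      }
      tangents <- tangentStructures(configs[[i]], curves, meshes[[i]])
      slidable <- which(!vapply(tangents, is.null, TRUE))
      if (!spec$slide_curves) slidable <- setdiff(slidable, curveRows)
      if (!spec$slide_surfaces) slidable <- setdiff(slidable, surfRows)
      delta <- .solveSlide(Y, refSpec, tangents, slidable, spec$criterion)
      step <- rep(0, nrow(Y))
      step[intersect(slidable, curveRows)] <- spec$stepsize
      step[intersect(slidable, surfRows)] <- spec$surface_stepsize
      Ynew <- Y + delta * step
      # pre-projection deviation of curve points from their polylines
      for (ci in seq_len(nrow(curves))) {
        pl <- polylines[[i]][[ci]]
        rows <- pl$curveRows
        if (!length(rows)) next
        proj <- .projectToPolyline(Ynew[rows, , drop = FALSE], pl$coords)
        curveDev <- curveDev + sum(sqrt(rowSums((proj - Ynew[rows, , drop = FALSE])^2)))
        Ynew[rows, ] <- proj
      }
      if (length(surfRows)) {
        np <- nearestPointOnMesh(meshes[[i]], Ynew[surfRows, , drop = FALSE])
        Ynew[surfRows, ] <- np$point
      }
      cfg <- configs[[i]]
      coords(cfg) <- Ynew
      newConfigs[[i]] <- cfg
    }
    meanDist <- mean(vapply(seq_len(n), function(i) {
      procrustesDistance(ref, newConfigs[[i]]@coords)
    }, 1))
    relChange <- if (is.na(lastDist) || lastDist == 0) Inf else abs(meanDist - lastDist) / lastDist
    trace <- rbind(trace, data.frame(
      iteration = iter, criterion = critSum / n,
      curve_deviation = curveDev / nCurvePts,
      mean_distance = meanDist, rel_change = relChange
    ))
    configs <- newConfigs
    lastDist <- meanDist
    if (is.finite(relChange) && relChange < spec$tolerance) break
  }
  list(configs = configs, trace = trace)
}
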