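# Seeded synthetic datasets: bilaterally symmetric configurations for
# mirroring experiments, and a two-group pyramid dataset for piecemeal /
# grouped sliding comparisons.

# Deterministic bilateral base shape: midline points on a sagittal arc plus
# right-side points on a lateral band; left side is the y-reflection.
.bilateralBase <- function(n_pairs, n_midline) {
  xm <- seq(-1, 1, length.out = n_midline)
  mid <- cbind(xm, 0, 0.5 * (1 - xm^2))
  u <- seq_len(n_pairs) / (n_pairs + 1L)
  right <- cbind(
    -1 + 2 * u,
    0.4 + 0.3 * sin(pi * u),
    0.2 * cos(2 * pi * u)
  )
  list(mid = mid, right = right)
}

#' Generate a bilaterally symmetric synthetic dataset
#'
#' Specimens share a symmetric base shape (midline points on the sagittal
#' plane, `n_pairs` bilateral point pairs) deformed by seeded symmetric shape
#' modes, plus independent digitizing noise on every coordinate (which breaks
#' exact symmetry) and, optionally, genuinely asymmetric modes. Bilateral
#' pairs are split across the three point classes so that one-sided,
#' landmark-completed, and fully mirrored analysis variants can be formed with
#' [bilateralVariant()].
#'
#' @param n_specimens number of specimens.
#' @param n_pairs bilateral point pairs (>= 6).
#' @param n_midline midline points (>= 3).
#' @param n_modes random symmetric deformation modes.
#' @param mode_sd standard deviation of the per-specimen mode coefficients.
#' @param noise_sd isotropic digitizing noise per coordinate.
#' @param asymmetry_sd standard deviation of asymmetric mode coefficients
#'   (0 = symmetric variation only).
#' @param midline_scale relative amplitude of the random modes on the midline
#'   points (midline structures are comparatively stable). The midline
#'   exaggeration artifact of one-side-only alignment emerges when bilateral
#'   points are numerous relative to the few midline points, as in
#'   high-density semilandmark data.
#' @param seed integer seed.
#' @return list with `configs` (list of [LandmarkConfig-class]), `pairs`
#'   (two-column left/right label matrix), `midline_labels`, and the drawn
#'   parameters in `manifest`.
#' @export
makeBilateralDataset <- function(n_specimens = 20L, n_pairs = 48L,
                                 n_midline = 5L, n_modes = 4L, mode_sd = 0.08,
                                 noise_sd = 0.01, asymmetry_sd = 0,
                                 midline_scale = 0.3, seed = 1L) {
  stopifnot(n_pairs >= 6L, n_midline >= 3L, n_specimens >= 2L)
  set.seed(seed)
  base <- .bilateralBase(n_pairs, n_midline)
  k <- seq_len(n_pairs)
  cls <- c("landmark", "curve", "surface")[(k - 1L) %% 3L + 1L]
  mkSide <- function(side) {
    tag <- if (side == "right") "r" else "l"
    isC <- cls == "curve"
    data.frame(
      label = sprintf("p%s_%02d", tag, k),
      class = cls, region = "body",
      curve_id = ifelse(isC, paste0("lat_", side), NA_character_),
      ordinal = ifelse(isC, cumsum(isC) - 1L, NA_integer_),
      side = side, stringsAsFactors = FALSE
    )
  }
  pts <- rbind(
    data.frame(
      label = sprintf("mid_%02d", seq_len(n_midline)), class = "landmark",
      region = "body", curve_id = NA_character_, ordinal = NA_integer_,
      side = "midline", stringsAsFactors = FALSE
    ),
    mkSide("right"), mkSide("left")
  )
  mirror <- function(m) cbind(m[, 1L], -m[, 2L], m[, 3L])
  baseXYZ <- rbind(base$mid, base$right, mirror(base$right))
  nPts <- nrow(baseXYZ)
  # symmetric modes: midline displacements stay in the sagittal plane,
  # left displacements mirror right ones
  symModes <- lapply(seq_len(n_modes), function(m) {
    dm <- midline_scale * cbind(rnorm(n_midline), 0, rnorm(n_midline))
    dr <- matrix(rnorm(3L * n_pairs), n_pairs, 3L)
    rbind(dm, dr, mirror(dr))
  })
  asymModes <- if (asymmetry_sd > 0) {
    lapply(seq_len(n_modes), function(m) matrix(rnorm(3L * nPts), nPts, 3L))
  } else {
    list()
  }
  configs <- vector("list", n_specimens)
  for (i in seq_len(n_specimens)) {
    xyz <- baseXYZ
    for (mode in symModes) xyz <- xyz + rnorm(1L, sd = mode_sd) * mode
    for (mode in asymModes) xyz <- xyz + rnorm(1L, sd = asymmetry_sd) * mode
    xyz <- xyz + matrix(rnorm(3L * nPts, sd = noise_sd), nPts, 3L)
    configs[[i]] <- LandmarkConfig(sprintf("spec%03d", i), pts, xyz)
  }
  names(configs) <- vapply(configs, specimenId, "")
  pairs <- cbind(
    left = sprintf("pl_%02d", k),
    right = sprintf("pr_%02d", k)
  )
  list(
    configs = configs, pairs = pairs,
    midline_labels = sprintf("mid_%02d", seq_len(n_midline)),
    manifest = list(
      n_specimens = n_specimens, n_pairs = n_pairs, n_midline = n_midline,
      n_modes = n_modes, mode_sd = mode_sd, noise_sd = noise_sd,
      asymmetry_sd = asymmetry_sd, midline_scale = midline_scale,
      seed = seed
    )
  )
}

#' Form an analysis variant of a bilateral configuration
#'
#' The four study designs for one-sided data: analyze the digitized side
#' alone; add the digitized left landmarks; additionally mirror the left
#' curve points from the right side; or mirror curve and surface points both
#' (left landmarks always stay as digitized). Mirroring reflects across the
#' least-squares midline plane via [mirrorFill()].
#'
#' @param config a full bilateral [LandmarkConfig-class].
#' @param pairs two-column (left, right) label matrix.
#' @param midline_labels midline point labels.
#' @param variant one of `"one_sided"`, `"left_landmarks"`,
#'   `"mirrored_curves"`, `"full_mirror"`.
#' @return A [LandmarkConfig-class] (left labels absent or imputed as chosen).
#' @export
bilateralVariant <- function(config, pairs, midline_labels,
                             variant = c(
                               "one_sided", "left_landmarks",
                               "mirrored_curves", "full_mirror"
                             )) {
  variant <- match.arg(variant)
  pts <- config@points
  cls <- pts$class[match(pairs[, 2L], pts$label)]
  keepDigitized <- switch(variant,
    one_sided = character(0),
    left_landmarks = ,
    mirrored_curves = ,
    full_mirror = pairs[cls == "landmark", 1L]
  )
  mirrored <- switch(variant,
    one_sided = character(0),
    left_landmarks = character(0),
    mirrored_curves = pairs[cls == "curve", 1L],
    full_mirror = pairs[cls != "landmark", 1L]
  )
  dropLabels <- setdiff(pairs[, 1L], c(keepDigitized, mirrored))
  out <- if (length(dropLabels)) dropPoints(config, dropLabels) else config
  if (length(mirrored)) {
    xyz <- out@coords
    xyz[mirrored, ] <- NA_real_
    coords(out) <- xyz
    sel <- pairs[, 1L] %in% mirrored
    out <- mirrorFill(out, pairs[sel, , drop = FALSE], midline_labels)
  }
  out
}

#' Generate a two-group pyramid dataset for grouped sliding comparisons
#'
#' Pyramids in two groups of distinctly different height ranges (a dominant
#' group and a small divergent group), each with fixed points plus directly
#' digitized surface points (a jittered grid projected onto the front face),
#' ready for sliding either all together or per group.
#'
#' @param n1,n2 group sizes.
#' @param seed integer seed.
#' @param surface_grid `c(rows, cols)` surface grid on the front face.
#' @param mesh_resolution target face count per specimen (kept low: the
#'   dataset exists to compare sliding workflows, not mesh detail).
#' @param curve_points points per edge curve.
#' @param jitter_sd jitter (in face coordinates) of the digitized surface
#'   grid, giving the sliding step genuine placement error to remove.
#' @return list with `configs`, `meshes`, `curves`, `groups` (factor), and
#'   `manifest`.
#' @export
makeTwoGroupDataset <- function(n1 = 30L, n2 = 10L, seed = 1L,
                                surface_grid = c(6L, 6L),
                                mesh_resolution = 900L, curve_points = 5L,
                                jitter_sd = 0.02) {
  set.seed(seed)
  n <- n1 + n2
  params <- data.frame(
    specimen = sprintf("two%03d", seq_len(n)),
    group = factor(rep(c("A", "B"), c(n1, n2))),
    base_depth = runif(n, 0.8, 1.2),
    height = c(runif(n1, 0.6, 1.0), runif(n2, 1.4, 2.0)),
    corner_skew = runif(n, -0.1, 0.1)
  )
  rows <- surface_grid[1L]
  cols <- surface_grid[2L]
  configs <- list()
  meshes <- list()
  curves <- NULL
  for (i in seq_len(n)) {
    p <- params[i, ]
    pyr <- makePyramid(
      base_width = 1, base_depth = p$base_depth, height = p$height,
      corner_skew = p$corner_skew, mesh_resolution = mesh_resolution,
      curve_points = curve_points, specimen_id = p$specimen
    )
    if (is.null(curves)) curves <- pyr$curves
    corners <- rbind(c(0, 0, 0), c(1, 0, 0))
    apex <- c((1 + p$corner_skew) / 2, p$base_depth / 2, p$height)
    sp <- matrix(0, rows * cols, 3L)
    m <- 0L
    for (r in seq_len(rows)) {
      for (cc in seq_len(cols)) {
        m <- m + 1L
        t_ <- min(max(cc / (cols + 1L) + rnorm(1L, sd = jitter_sd), 0.05), 0.95)
        s_ <- min(max(r / (rows + 1L) + rnorm(1L, sd = jitter_sd), 0.05), 0.95)
        sp[m, ] <- .pyramidFacePoint(corners, apex, t_, s_)
      }
    }
    sp <- nearestPointOnMesh(pyr$mesh, sp)$point
    frag <- LandmarkConfig(
      "",
      data.frame(
        label = sprintf("surf_%03d", seq_len(rows * cols)), class = "surface",
        region = "face1", curve_id = NA_character_, ordinal = NA_integer_,
        side = "none", stringsAsFactors = FALSE
      ),
      sp
    )
    configs[[p$specimen]] <- appendPoints(pyr$config, frag)
    meshes[[p$specimen]] <- pyr$mesh
  }
  list(
    configs = configs, meshes = meshes, curves = curves,
    groups = stats::setNames(params$group, params$specimen),
    manifest = list(
      seed = seed, params = params, surface_grid = surface_grid,
      mesh_resolution = mesh_resolution, curve_points = curve_points,
      jitter_sd = jitter_sd
    )
  )
}
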