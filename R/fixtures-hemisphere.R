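# Hemisphere ("dome") template fixture at a controllable face count, for
# exercising template resolution effects.

#' Generate a hemispherical template
#'
#' Builds a closed mesh of a solid hemisphere (dome plus flat base) near a
#' target triangle count, with landmarks at the apex and at four rim
#' positions, four quarter-rim curves bounding the dome, and a latitude /
#' longitude grid of surface points over the dome. High face counts (the
#' upper working range is around 18,000 faces) make ray projections
#' accurate; the same template at a tenth of the count shows the cost of a
#' coarse template.
#'
#' @param radius hemisphere radius.
#' @param target_faces approximate total face count.
#' @param surface_grid `c(rows, cols)` of dome surface points.
#' @param rim_points curve points per quarter-rim arc (endpoints included).
#' @param specimen_id identifier.
#' @return list with `mesh`, `config`, `curves`, ready for [buildAtlas()].
#' @export
makeHemisphereTemplate <- function(radius = 1, target_faces = 18000L,
                                   surface_grid = c(9L, 10L), rim_points = 8L,
                                   specimen_id = "dome") {
  stopifnot(radius > 0, target_faces >= 24L)
  S <- max(8L, as.integer(round(sqrt(target_faces / 2))))
  R1 <- max(2L, as.integer(ceiling(0.75 * S))) # dome latitude rings
  R2 <- max(2L, as.integer(ceiling(0.25 * S))) # base concentric rings
  theta <- 2 * pi * (seq_len(S) - 1L) / S
  ring <- function(r, z) cbind(r * cos(theta), r * sin(theta), z)
  V <- rbind(c(0, 0, radius))
  ringStart <- integer(0)
  for (i in seq_len(R1)) { # phi from pole toward rim; i = R1 is the rim
    phi <- (pi / 2) * i / R1
    ringStart <- c(ringStart, nrow(V) + 1L)
    V <- rbind(V, ring(radius * sin(phi), radius * cos(phi)))
  }
  for (j in (R2 - 1L):1L) { # base rings from just inside the rim inward
    ringStart <- c(ringStart, nrow(V) + 1L)
    V <- rbind(V, ring(radius * j / R2, 0))
  }
  centerIdx <- nrow(V) + 1L
  V <- rbind(V, c(0, 0, 0))
  F_ <- list()
  nxt <- function(s) c(seq_len(S)[-1L], 1L)
  # apex fan
  for (s in seq_len(S)) {
    F_[[length(F_) + 1L]] <- c(1L, ringStart[1L] + s - 1L, ringStart[1L] + (s %% S))
  }
  # bands between consecutive rings (dome rings then base rings share order)
  for (b in seq_len(length(ringStart) - 1L)) {
    a0 <- ringStart[b]
    b0 <- ringStart[b + 1L]
    for (s in seq_len(S)) {
      s2 <- s %% S + 1L
      F_[[length(F_) + 1L]] <- c(a0 + s - 1L, b0 + s - 1L, b0 + s2 - 1L)
      F_[[length(F_) + 1L]] <- c(a0 + s - 1L, b0 + s2 - 1L, a0 + s2 - 1L)
    }
  }
  # innermost base ring to center fan
  inner <- ringStart[length(ringStart)]
  for (s in seq_len(S)) {
    F_[[length(F_) + 1L]] <- c(inner + s - 1L, centerIdx, inner + (s %% S))
  }
  mesh <- TriMesh(V, do.call(rbind, F_))
  # landmarks: apex + four rim compass points
  lm <- rbind(
    apex = c(0, 0, radius),
    rim_e = c(radius, 0, 0), rim_n = c(0, radius, 0),
    rim_w = c(-radius, 0, 0), rim_s = c(0, -radius, 0)
  )
  pts <- data.frame(
    label = rownames(lm), class = "landmark", region = "dome",
    curve_id = NA_character_, ordinal = NA_integer_, side = "none",
    stringsAsFactors = FALSE
  )
  xyz <- lm
  arcs <- list(
    rim_en = c("rim_e", "rim_n"), rim_nw = c("rim_n", "rim_w"),
    rim_ws = c("rim_w", "rim_s"), rim_se = c("rim_s", "rim_e")
  )
  curves <- do.call(rbind, lapply(names(arcs), function(a) {
    curveDefinition(a, arcs[[a]][1L], arcs[[a]][2L], rim_points)
  }))
  arcStart <- c(rim_en = 0, rim_nw = pi / 2, rim_ws = pi, rim_se = 3 * pi / 2)
  for (a in names(arcs)) {
    th <- arcStart[[a]] + (pi / 2) * seq_len(rim_points - 2L) / (rim_points - 1L)
    inner <- cbind(radius * cos(th), radius * sin(th), 0)
    ni <- nrow(inner)
    pts <- rbind(pts, data.frame(
      label = sprintf("%s_%02d", a, seq_len(ni)), class = "curve",
      region = "dome", curve_id = a, ordinal = seq_len(ni) - 1L,
      side = "none", stringsAsFactors = FALSE
    ))
    xyz <- rbind(xyz, inner)
  }
  rows <- surface_grid[1L]
  cols <- surface_grid[2L]
  sp <- list()
  for (i in seq_len(rows)) {
    phi <- (pi / 2) * i / (rows + 1L)
    for (j in seq_len(cols)) {
      th <- 2 * pi * (j - 0.5) / cols
      sp[[length(sp) + 1L]] <- radius * c(
        sin(phi) * cos(th), sin(phi) * sin(th), cos(phi)
      )
    }
  }
  sp <- nearestPointOnMesh(mesh, do.call(rbind, sp))$point
  ns <- nrow(sp)
  pts <- rbind(pts, data.frame(
    label = sprintf("surf_%03d", seq_len(ns)), class = "surface",
    region = "dome", curve_id = NA_character_, ordinal = NA_integer_,
    side = "none", stringsAsFactors = FALSE
  ))
  # snap every point onto the discretized surface (the analytic sphere and
  # its chordal mesh differ by the sagitta of one facet)
  xyz <- nearestPointOnMesh(mesh, rbind(xyz, sp))$point
  config <- LandmarkConfig(specimen_id, pts, xyz)
  validObject(config)
  list(mesh = mesh, config = config, curves = curves)
}
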