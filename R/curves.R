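#' Resample a polyline to evenly spaced points
#'
#' Returns `n` points on the input polyline with equal chord-length spacing
#' along it. The first and last output points coincide with the polyline
#' endpoints, so landmark anchors are never moved. Manually digitized curve
#' points are rarely evenly spaced, and the curve-point budget is usually
#' revised, so every curve is resampled this way before sliding.
#'
#' @param polyline numeric p x 3 matrix of ordered points (p >= 2).
#' @param n integer >= 2, number of output points (including both endpoints).
#' @return numeric n x 3 matrix of points on the polyline.
#' @export
resampleCurve <- function(polyline, n) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2L) stop("polyline needs at least 2 points")
  if (n < 2L) stop("n must be >= 2")
  seg <- diff(polyline)
  seglen <- sqrt(rowSums(seg^2))
  total <- sum(seglen)
  if (total <= 0) stop("zero-length polyline")
  cum <- c(0, cumsum(seglen))
  s <- seq(0, total, length.out = n)
  # locate each target arc length on its segment
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(seglen))
  frac <- (s - cum[idx]) / seglen[idx]
  frac[seglen[idx] == 0] <- 0
  out <- polyline[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  out[1L, ] <- polyline[1L, ]
  out[n, ] <- polyline[nrow(polyline), ]
  out
}

#' Allocate a curve-point budget across curves by length
#'
#' Distributes `total_budget` points over curves proportionally to their
#' lengths using largest-remainder rounding, then clips each count to
#' `[min_per_curve, max_per_curve]` and redistributes any clipped surplus.
#' Long anatomical outlines receive more points, but each curve is capped
#' (default 30) because oversampling curves impedes the patching step; the
#' default minimum is 5, which does not hurt patching success.
#'
#' Alternatively, `spacing` allocates by a target inter-point distance so
#' curve-point density can be matched to the surface-point density.
#'
#' @param curve_lengths numeric vector of curve lengths.
#' @param total_budget integer total number of points to allocate (ignored
#'   when `spacing` is given).
#' @param min_per_curve,max_per_curve integer per-curve bounds.
#' @param spacing optional target spacing; counts become
#'   `round(length / spacing) + 1`, clipped to the same bounds.
#' @return integer vector of per-curve counts.
#' @export
allocateCurvePoints <- function(curve_lengths, total_budget = NULL,
                                min_per_curve = 5L, max_per_curve = 30L,
                                spacing = NULL) {
  k <- length(curve_lengths)
  if (!is.null(spacing)) {
    if (spacing <= 0) stop("spacing must be positive")
    n <- pmin(pmax(as.integer(round(curve_lengths / spacing)) + 1L, min_per_curve), max_per_curve)
    return(n)
  }
  if (is.null(total_budget)) stop("give either total_budget or spacing")
  lo <- sum(rep(min_per_curve, k))
  hi <- sum(rep(max_per_curve, k))
  if (total_budget < lo || total_budget > hi) {
    stop(sprintf(
      "budget %d infeasible for %d curves with bounds [%d, %d]",
      total_budget, k, min_per_curve, max_per_curve
    ))
  }
  # largest-remainder apportionment, then iterative clipping
  n <- rep(NA_integer_, k)
  free <- rep(TRUE, k)
  budget <- total_budget
  repeat {
    w <- curve_lengths[free] / sum(curve_lengths[free])
    quota <- w * budget
    base <- floor(quota)
    rem <- budget - sum(base)
    add <- integer(sum(free))
    if (rem > 0) add[order(quota - base, decreasing = TRUE)[seq_len(rem)]] <- 1L
    prop <- as.integer(base + add)
    clip <- pmin(pmax(prop, min_per_curve), max_per_curve)
    if (all(clip == prop)) {
      n[free] <- prop
      break
    }
    fixed <- which(free)[clip != prop]
    n[fixed] <- clip[clip != prop]
    free[fixed] <- FALSE
    budget <- total_budget - sum(n[!free])
    if (!any(free)) break
  }
  # rounding slack after clipping: nudge feasible counts to conserve budget
  slack <- total_budget - sum(n)
  while (slack != 0) {
    if (slack > 0) {
      i <- which(n < max_per_curve)[which.max(curve_lengths[n < max_per_curve])]
      n[i] <- n[i] + 1L
      slack <- slack - 1L
    } else {
      i <- which(n > min_per_curve)[which.min(curve_lengths[n > min_per_curve])]
      n[i] <- n[i] - 1L
      slack <- slack + 1L
    }
  }
  n
}

#' Build a curve definition table
#'
#' @param curve_id character ids.
#' @param start_landmark,end_landmark anchor landmark labels (identical for a
#'   closed curve).
#' @param n_points integer resampling budget per curve, endpoints included.
#' @param closed logical; closed curves are fences around holes.
#' @return data.frame usable as the `curves` slot of an [Atlas-class].
#' @export
curveDefinition <- function(curve_id, start_landmark, end_landmark, n_points,
                            closed = FALSE) {
  stopifnot(all(n_points >= 2L | closed))
  data.frame(
    curve_id = as.character(curve_id),
    start_landmark = as.character(start_landmark),
    end_landmark = as.character(end_landmark),
    n_points = as.integer(n_points),
    closed = as.logical(closed),
    stringsAsFactors = FALSE
  )
}

# Ordered polyline (anchor, curve points, anchor) for one curve of a config.
.curvePolyline <- function(config, curve) {
  pts <- config@points
  sel <- which(pts$class == "curve" & pts$curve_id == curve$curve_id)
  sel <- sel[order(pts$ordinal[sel])]
  start <- which(pts$label == curve$start_landmark)
  end <- which(pts$label == curve$end_landmark)
  if (!length(start) || !length(end)) {
    stop("curve anchors not found for curve ", curve$curve_id)
  }
  rows <- c(start, sel, end)
  list(coords = config@coords[rows, , drop = FALSE], curveRows = sel)
}
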