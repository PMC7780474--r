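# Independent brute-force oracles, implemented in plain R with different
# algorithms than the package's compiled kernels.

# Closest point on a triangle: project onto the plane; if the projection is
# inside, it is optimal, otherwise the optimum is the nearest point on one of
# the three edges (each solved as clamped 1-D projection).
oracleClosestOnTriangle <- function(q, A, B, C) {
  segClosest <- function(p, a, b) {
    d <- b - a
    L2 <- sum(d^2)
    t <- if (L2 == 0) 0 else max(0, min(1, sum((p - a) * d) / L2))
    a + t * d
  }
  n <- c(
    (B - A)[2] * (C - A)[3] - (B - A)[3] * (C - A)[2],
    (B - A)[3] * (C - A)[1] - (B - A)[1] * (C - A)[3],
    (B - A)[1] * (C - A)[2] - (B - A)[2] * (C - A)[1]
  )
  n2 <- sum(n^2)
  candidates <- list(
    segClosest(q, A, B), segClosest(q, B, C), segClosest(q, C, A)
  )
  if (n2 > 0) {
    p <- q - (sum((q - A) * n) / n2) * n
    # barycentric test of the plane projection
    M <- cbind(B - A, C - A)
    uv <- tryCatch(qr.solve(crossprod(M), crossprod(M, p - A)), error = function(e) NULL)
    if (!is.null(uv) && uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1) {
      candidates <- c(candidates, list(p))
    }
  }
  d2 <- vapply(candidates, function(x) sum((q - x)^2), 1)
  candidates[[which.min(d2)]]
}

# Brute force over all faces.
oracleClosestPointOnMesh <- function(mesh, q) {
  V <- semiland::vertices(mesh)
  F_ <- semiland::faces(mesh)
  best <- NULL
  bestD2 <- Inf
  bestFace <- NA_integer_
  for (i in seq_len(nrow(F_))) {
    p <- oracleClosestOnTriangle(q, V[F_[i, 1], ], V[F_[i, 2], ], V[F_[i, 3], ])
    d2 <- sum((q - p)^2)
    if (d2 < bestD2) {
      bestD2 <- d2
      best <- p
      bestFace <- i
    }
  }
  list(point = best, distance = sqrt(bestD2), face = bestFace)
}

# Line-triangle intersections by solving the 3x3 linear system
# origin + t*dir = A + u*(B-A) + v*(C-A) for every face.
oracleRayHits <- function(mesh, origin, dir) {
  V <- semiland::vertices(mesh)
  F_ <- semiland::faces(mesh)
  eps <- 1e-9
  hits <- list()
  for (i in seq_len(nrow(F_))) {
    A <- V[F_[i, 1], ]
    B <- V[F_[i, 2], ]
    C <- V[F_[i, 3], ]
    M <- cbind(-dir, B - A, C - A)
    if (abs(det(M)) < 1e-14) next
    s <- solve(M, origin - A)
    t <- s[1]
    u <- s[2]
    v <- s[3]
    if (u >= -eps && v >= -eps && u + v <= 1 + eps) {
      hits[[length(hits) + 1L]] <- c(t = t, face = i)
    }
  }
  if (!length(hits)) {
    return(data.frame(t = numeric(0), face = integer(0)))
  }
  out <- as.data.frame(do.call(rbind, hits))
  out[order(abs(out$t)), , drop = FALSE]
}

# Dense arc-length resampling oracle: sample the polyline very finely, then
# read off points at the target cumulative lengths.
oracleResample <- function(polyline, n, dense = 20000L) {
  seg <- diff(polyline)
  seglen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  s <- seq(0, total, length.out = dense)
  densePts <- t(vapply(s, function(si) {
    j <- max(1L, min(findInterval(si, cum, rightmost.closed = TRUE), nrow(seg)))
    frac <- if (seglen[j] == 0) 0 else (si - cum[j]) / seglen[j]
    polyline[j, ] + frac * seg[j, ]
  }, numeric(3)))
  target <- seq(0, total, length.out = n)
  densePts[vapply(target, function(ti) which.min(abs(s - ti)), 1L), , drop = FALSE]
}

# Independent TPS bending energy: fit the interpolating spline weights by
# solving the full system directly, then evaluate w' K w per coordinate.
oracleBendingEnergy <- function(src, dst) {
  k <- nrow(src)
  K <- -as.matrix(dist(src))
  P <- cbind(1, src)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(dst, matrix(0, 4, 3))
  sol <- solve(L, rhs)
  W <- sol[seq_len(k), , drop = FALSE]
  sum(diag(t(W) %*% K %*% W))
}
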