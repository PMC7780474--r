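# Semilandmark sliding

# Pyramid-based sliding fixture: landmarks + straight edge curves (optionally
# surface points), with a "truth" configuration and perturbed copies.
slideFixture <- function(n_specimens = 1, perturb = 0, seed = 1,
                         surface = FALSE) {
  pyr <- if (surface) {
    makePyramid(mesh_resolution = 700L, surface_grid = c(3L, 3L))
  } else {
    fixPlainPyramid()
  }
  truth <- pyr$config
  set.seed(seed)
  configs <- lapply(seq_len(n_specimens), function(i) {
    cfg <- truth
    cfg@specimenId <- sprintf("s%02d", i)
    if (perturb > 0) {
      xyz <- coords(cfg)
      info <- pointInfo(cfg)
      tg <- tangentStructures(cfg, pyr$curves, pyr$mesh)
      for (r in which(info$class != "landmark")) {
        if (is.null(tg[[r]])) next
        xyz[r, ] <- xyz[r, ] + as.vector(tg[[r]] %*% rnorm(ncol(tg[[r]]), sd = perturb))
      }
      coords(cfg) <- xyz
    }
    cfg
  })
  names(configs) <- vapply(configs, specimenId, "")
  list(
    pyr = pyr, truth = truth, configs = configs,
    meshes = stats::setNames(rep(list(pyr$mesh), n_specimens), names(configs))
  )
}

test_that("tangent structures follow curves and surfaces", {
  fx <- slideFixture(surface = TRUE)
  tg <- tangentStructures(fx$truth, fx$pyr$curves, fx$pyr$mesh)
  info <- pointInfo(fx$truth)
  expect_true(all(vapply(tg[info$class == "landmark"], is.null, TRUE)))
  # edge_front runs along +x: tangents parallel to the x axis
  for (r in which(info$curve_id %in% "edge_front")) {
    expect_equal(abs(tg[[r]][, 1]), c(1, 0, 0), tolerance = 1e-12)
  }
  # surface tangent pairs are orthonormal and perpendicular to the face normal
  fn <- rayMeshIntersections(fx$pyr$mesh, coords(fx$truth)["surf_001", ] +
    1e-4 * vertexNormals(fx$pyr$mesh)[1, ], c(0, -1, 0))
  for (r in which(info$class == "surface")) {
    D <- tg[[r]]
    expect_equal(unname(crossprod(D)), diag(2), tolerance = 1e-10)
  }
  # closed curves (the fossa fence) have tangents everywhere
  pyrF <- fixPyramid()
  tgF <- tangentStructures(pyrF$config, pyrF$curves, pyrF$mesh)
  infoF <- pointInfo(pyrF$config)
  fenceRows <- which(infoF$curve_id %in% "fence")
  expect_true(all(!vapply(tgF[fenceRows], is.null, TRUE)))
  expect_error(
    tangentStructures(pyrF$config, pyrF$curves, NULL),
    "mesh required"
  )
})

test_that("bending-energy objective is non-increasing at stepsize 1 pre-projection", {
  fx <- slideFixture(n_specimens = 4, perturb = 0.04, seed = 21)
  sl <- slideSemilandmarks(fx$configs, fx$meshes, fx$pyr$curves,
    spec = slidingSpec(
      stepsize = 1, max_iterations = 8L, tolerance = 0,
      reference_mode = "fixed_reference"
    ),
    reference = fx$truth
  )
  tr <- sl$trace
  expect_true(all(diff(tr$criterion) <= 1e-8 * (tr$criterion[1] + 1e-300)))
  # curve points stay on straight edges: pre-projection deviation is tiny
  expect_lt(max(tr$curve_deviation), 1e-8)
})

test_that("planted displacement along a straight curve is recovered", {
  fx <- slideFixture()
  start <- fx$truth
  xyz <- coords(start)
  info <- pointInfo(start)
  victim <- which(info$curve_id %in% "edge_front")[2]
  xyz[victim, ] <- xyz[victim, ] + c(0.11, 0, 0) # along the bottom front edge
  coords(start) <- xyz
  sl <- slideSemilandmarks(
    list(s1 = start), list(s1 = fx$pyr$mesh), fx$pyr$curves,
    spec = slidingSpec(
      stepsize = 1, max_iterations = 25L, tolerance = 0,
      reference_mode = "fixed_reference"
    ),
    reference = fx$truth
  )
  got <- coords(sl$configs[[1]])
  expect_lt(max(abs(got - coords(fx$truth))), 1e-6)
})

test_that("procrustes-distance criterion also recovers the planted point", {
  fx <- slideFixture()
  start <- fx$truth
  xyz <- coords(start)
  victim <- which(pointInfo(start)$curve_id %in% "edge_back")[1]
  xyz[victim, ] <- xyz[victim, ] + 0.1 * c(-1, 0, 0)
  coords(start) <- xyz
  sl <- slideSemilandmarks(
    list(s1 = start), list(s1 = fx$pyr$mesh), fx$pyr$curves,
    spec = slidingSpec(
      criterion = "procrustes_distance", stepsize = 1,
      max_iterations = 25L, tolerance = 0, reference_mode = "fixed_reference"
    ),
    reference = fx$truth
  )
  expect_lt(max(abs(coords(sl$configs[[1]]) - coords(fx$truth))), 1e-4)
})

test_that("stepsize 0 is a no-op", {
  fx <- slideFixture(n_specimens = 2, perturb = 0.05, seed = 3, surface = TRUE)
  sl <- slideSemilandmarks(fx$configs, fx$meshes, fx$pyr$curves,
    spec = slidingSpec(stepsize = 0, surface_stepsize = 0, max_iterations = 3L)
  )
  for (nm in names(fx$configs)) {
    expect_lt(max(abs(coords(sl$configs[[nm]]) - coords(fx$configs[[nm]]))), 1e-9)
  }
  expect_error(slidingSpec(stepsize = -0.1), "stepsize")
  expect_error(slidingSpec(stepsize = 2), "stepsize")
})

test_that("sliding reduces planted tangential noise across a sample", {
  fx <- slideFixture(n_specimens = 5, perturb = 0.05, seed = 8, surface = TRUE)
  before <- mean(vapply(fx$configs, function(c) {
    procrustesDistance(coords(c), coords(fx$truth))
  }, 1))
  sl <- slideSemilandmarks(fx$configs, fx$meshes, fx$pyr$curves,
    spec = slidingSpec(max_iterations = 15L)
  )
  tr <- sl$trace
  expect_true(all(c(
    "iteration", "criterion", "curve_deviation", "mean_distance", "rel_change"
  ) %in% names(tr)))
  # mean Procrustes distance to the evolving mean decreases
  expect_lt(tr$mean_distance[nrow(tr)], tr$mean_distance[1])
  # class switches freeze the respective points
  slC <- slideSemilandmarks(fx$configs, fx$meshes, fx$pyr$curves,
    spec = slidingSpec(max_iterations = 2L, slide_surfaces = FALSE)
  )
  surfRows <- pointInfo(fx$truth)$class == "surface"
  expect_equal(
    coords(slC$configs[[1]])[surfRows, ],
    coords(fx$configs[[1]])[surfRows, ],
    tolerance = 1e-9
  )
})

test_that("fixed_reference mode requires a reference", {
  fx <- slideFixture()
  expect_error(
    slideSemilandmarks(
      list(s1 = fx$truth), list(s1 = fx$pyr$mesh), fx$pyr$curves,
      spec = slidingSpec(reference_mode = "fixed_reference")
    ),
    "needs a reference"
  )
})
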