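# Synthetic fixture generators

test_that("makePyramid produces a consistent template", {
  pyr <- fixPyramid()
  expect_s4_class(pyr$mesh, "TriMesh")
  # face count lands near the requested resolution
  expect_lt(abs(nFaces(pyr$mesh) - 1000) / 1000, 0.3)
  # every configuration point is on the mesh surface
  np <- nearestPointOnMesh(pyr$mesh, coords(pyr$config))
  expect_lt(max(np$distance), 1e-6)
  info <- pointInfo(pyr$config)
  expect_setequal(
    info$label[info$class == "landmark"],
    c("apex", "base_fl", "base_fr", "base_br", "base_bl", "fence_anchor")
  )
  # corner landmarks coincide with the defining vertices
  expect_equal(unname(coords(pyr$config)["base_fl", ]), c(0, 0, 0))
  expect_equal(unname(coords(pyr$config)["base_fr", ]), c(1, 0, 0))
  expect_equal(unname(coords(pyr$config)["apex", ]), c(0.5, 0.5, 1))
  # 8 edge curves plus the fence
  expect_setequal(
    unique(na.omit(info$curve_id)),
    c(
      "edge_front", "edge_right", "edge_back", "edge_left",
      "rise_fl", "rise_fr", "rise_br", "rise_bl", "fence"
    )
  )
  expect_equal(sum(info$class == "surface"), 20) # 4 x 5 grid
})

test_that("the fossa depresses the front face; the fence is fossa-sized", {
  pyr <- fixPyramid()
  plain <- fixPlainPyramid()
  # cast a ray through the fossa center (the centroid of the rim fence)
  # from outside, along +y; the anchor itself sits on the rim where the
  # depression vanishes
  fenceAll <- coords(pyr$config)[
    grep("^fence", rownames(coords(pyr$config))), ,
    drop = FALSE
  ]
  center3d <- colMeans(fenceAll)
  origin <- c(center3d[1], -2, center3d[3])
  hitF <- rayMeshIntersections(pyr$mesh, origin, c(0, 1, 0))
  hitP <- rayMeshIntersections(plain$mesh, origin, c(0, 1, 0))
  # the fossa surface lies deeper (farther along +y) than the plain face
  expect_gt(min(hitF$t) - min(hitP$t), 0.01)
  # the fence circles the fossa rim: diameter ~ 2 x fossa radius
  fence <- coords(pyr$config)[grep("^fence_\\d", rownames(coords(pyr$config))), ]
  expect_lt(abs(max(dist(fence)) - 0.28), 0.06)
  # fossa exceeding the face errors
  expect_error(
    makePyramid(
      fossa = list(center = c(0.5, 0.5), radius = 0.9),
      mesh_resolution = 500L
    ),
    "exceeds the front face"
  )
})

test_that("makeHemisphereTemplate hits requested face counts", {
  hi <- makeHemisphereTemplate(target_faces = 18000L)
  expect_lt(abs(nFaces(hi$mesh) - 18000) / 18000, 0.10)
  lo <- makeHemisphereTemplate(target_faces = 1800L, surface_grid = c(5L, 6L))
  expect_lt(abs(nFaces(lo$mesh) - 1800) / 1800, 0.10)
  # all template points on surface; atlas builds without resolution warning
  np <- nearestPointOnMesh(hi$mesh, coords(hi$config))
  expect_lt(max(np$distance), 1e-6)
  expect_no_warning(buildAtlas(hi$mesh, hi$config, hi$curves))
  expect_warning(
    buildAtlas(lo$mesh, lo$config, lo$curves),
    "deform poorly"
  )
  info <- pointInfo(hi$config)
  expect_equal(sum(info$class == "surface"), 90)
  # rim landmarks sit on the equator (radius within one facet sagitta)
  rim <- coords(hi$config)[c("rim_e", "rim_n", "rim_w", "rim_s"), ]
  expect_lt(max(abs(rim[, 3])), 1e-9)
  expect_equal(unname(sqrt(rowSums(rim^2))), rep(1, 4), tolerance = 1e-3)
})

test_that("bilateral dataset is exactly symmetric without noise", {
  bd <- makeBilateralDataset(
    n_specimens = 4, n_pairs = 8, noise_sd = 0, asymmetry_sd = 0, seed = 11
  )
  expect_length(bd$configs, 4)
  for (cfg in bd$configs) {
    xyz <- coords(cfg)
    L <- xyz[bd$pairs[, 1], , drop = FALSE]
    R <- xyz[bd$pairs[, 2], , drop = FALSE]
    mirrored <- R
    mirrored[, 2] <- -mirrored[, 2]
    expect_lt(max(abs(L - mirrored)), 1e-12)
    # midline stays in the sagittal plane
    expect_lt(max(abs(xyz[bd$midline_labels, 2])), 1e-12)
  }
  # asymmetry breaks the exact mirror relation
  bdA <- makeBilateralDataset(
    n_specimens = 2, n_pairs = 8, noise_sd = 0, asymmetry_sd = 0.05, seed = 11
  )
  xyz <- coords(bdA$configs[[1]])
  L <- xyz[bdA$pairs[, 1], ]
  R <- xyz[bdA$pairs[, 2], ]
  R[, 2] <- -R[, 2]
  expect_gt(max(abs(L - R)), 1e-3)
  # point classes interleave landmark / curve / surface
  info <- pointInfo(bd$configs[[1]])
  expect_setequal(unique(info$class), c("landmark", "curve", "surface"))
})

test_that("two-group dataset separates heights and stays on-mesh", {
  tg <- cached("two_group_small", function() {
    semiland::makeTwoGroupDataset(
      n1 = 4, n2 = 3, seed = 7,
      surface_grid = c(3L, 3L), mesh_resolution = 500L
    )
  })
  expect_equal(as.vector(table(tg$groups)), c(4L, 3L))
  expect_setequal(names(tg$configs), names(tg$meshes))
  hA <- vapply(names(tg$groups)[tg$groups == "A"], function(s) {
    max(coords(tg$configs[[s]])[, 3])
  }, 1)
  hB <- vapply(names(tg$groups)[tg$groups == "B"], function(s) {
    max(coords(tg$configs[[s]])[, 3])
  }, 1)
  expect_lt(max(hA), min(hB)) # group B pyramids are taller
  for (s in names(tg$configs)) {
    np <- nearestPointOnMesh(tg$meshes[[s]], coords(tg$configs[[s]]))
    expect_lt(max(np$distance), 1e-6)
  }
})

test_that("pyramid experiment bundle is correctly structured", {
  ex <- cached("pyr_experiment_small", function() {
    semiland::makePyramidExperiment(
      seed = 5, mesh_resolution = 900L,
      template_resolution = 1200L, curve_points = 4L
    )
  })
  expect_length(ex$specimens, 10)
  withFossa <- vapply(ex$specimens, function(s) isTRUE(s$fossa), TRUE)
  expect_equal(sum(withFossa), 4)
  expect_gt(length(ex$fence_labels), 0)
  # the no-hole atlas lacks exactly the fence labels
  full <- pointInfo(ex$template@config)$label
  nofence <- pointInfo(ex$template_nohole@config)$label
  expect_setequal(setdiff(full, nofence), ex$fence_labels)
  expect_equal(sum(grepl("^surf_", full)), 90)
})
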