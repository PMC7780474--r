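# Atlas construction and surface-point patching

fixedOnly <- function(config) {
  dropPoints(config, function(p) p$class == "surface")
}

test_that("buildAtlas validates on-surface points and resolution", {
  pyr <- fixPyramid()
  expect_warning(
    buildAtlas(pyr$mesh, pyr$config, pyr$curves),
    "deform poorly"
  )
  atlas <- suppressWarnings(buildAtlas(pyr$mesh, pyr$config, pyr$curves))
  expect_s4_class(atlas, "Atlas")
  bad <- pyr$config
  xyz <- coords(bad)
  xyz["surf_003", ] <- xyz["surf_003", ] + c(0, -0.3, 0)
  coords(bad) <- xyz
  expect_error(
    suppressWarnings(buildAtlas(pyr$mesh, bad, pyr$curves)),
    "off the template surface: surf_003"
  )
})

test_that("patching the template onto itself reproduces the template", {
  pyr <- fixPyramid()
  atlas <- suppressWarnings(buildAtlas(pyr$mesh, pyr$config, pyr$curves))
  res <- placePatch(atlas, pyr$mesh, fixedOnly(pyr$config))
  expect_false(res@failed)
  surfLabels <- grep("^surf_", pointInfo(pyr$config)$label, value = TRUE)
  expect_lt(
    max(abs(coords(res@config)[surfLabels, ] - coords(pyr$config)[surfLabels, ])),
    1e-6
  )
  # canonical order preserved
  expect_equal(pointInfo(res@config)$label, pointInfo(pyr$config)$label)
  d <- res@diagnostics
  expect_equal(names(d), c("label", "distance", "normalAgreement", "method", "offRegion"))
  expect_true(all(d$method %in% c("ray_neg", "ray_pos", "nearest")))
  expect_lt(max(d$distance), 1e-8)
  expect_false(any(d$offRegion))
})

test_that("inflation along flat faces deflates back to the same points", {
  pyr <- fixPyramid()
  atlas <- suppressWarnings(buildAtlas(pyr$mesh, pyr$config, pyr$curves))
  surfLabels <- grep("^surf_", pointInfo(pyr$config)$label, value = TRUE)
  for (mode in c("absolute", "relative")) {
    res <- placePatch(atlas, pyr$mesh, fixedOnly(pyr$config),
      inflate = 0.05, inflate_mode = mode
    )
    expect_false(res@failed)
    # surface points on planar facets return exactly along the ray
    expect_lt(
      max(abs(coords(res@config)[surfLabels, ] - coords(pyr$config)[surfLabels, ])),
      1e-6
    )
    expect_lt(max(res@diagnostics$distance), 1e-8)
  }
})

test_that("patching transfers surface points to a deformed specimen", {
  pyr <- fixPyramid()
  atlas <- suppressWarnings(buildAtlas(pyr$mesh, pyr$config, pyr$curves))
  spec <- makePyramid(
    base_depth = 1.3, height = 1.6, corner_skew = 0.1,
    fossa = list(center = c(0.5, 0.35), radius = 0.14),
    mesh_resolution = 1000L, specimen_id = "spec"
  )
  res <- placePatch(atlas, spec$mesh, fixedOnly(spec$config), inflate = 0.02)
  expect_false(res@failed)
  d <- res@diagnostics
  # every placement lands on the specimen surface
  expect_lt(max(d$distance), 1e-6 * max(abs(vertices(spec$mesh))))
  expect_true(all(d$normalAgreement > 0))
  expect_false(any(d$offRegion))
  # relaxation variant also succeeds and stays on the surface
  resR <- placePatch(atlas, spec$mesh, fixedOnly(spec$config),
    inflate = 0.02, relax_to_atlas = TRUE
  )
  expect_false(resR@failed)
  np <- nearestPointOnMesh(spec$mesh, coords(resR@config)[d$label, ])
  expect_lt(max(np$distance), 1e-6)
})

test_that("label mismatches error; floating fixed points fail as values", {
  pyr <- fixPyramid()
  atlas <- suppressWarnings(buildAtlas(pyr$mesh, pyr$config, pyr$curves))
  fixed <- fixedOnly(pyr$config)
  expect_error(
    placePatch(atlas, pyr$mesh, dropPoints(fixed, "apex")),
    "do not match the atlas: missing \\{apex\\}"
  )
  floating <- fixed
  xyz <- coords(floating)
  xyz["apex", ] <- xyz["apex", ] + c(0, 0, 0.5)
  coords(floating) <- xyz
  res <- placePatch(atlas, pyr$mesh, floating)
  expect_true(res@failed)
  expect_match(res@reason, "floating fixed points")
  expect_match(res@reason, "apex")
})

test_that("piecemeal patching merges regions and matches the global patch", {
  pyr <- fixPyramid()
  cfg <- pyr$config
  pts <- pointInfo(cfg)
  surfIdx <- which(pts$class == "surface")
  pts$region[pts$class != "surface"] <- "rA"
  pts$region[surfIdx[seq_len(10)]] <- "rA"
  pts$region[surfIdx[-seq_len(10)]] <- "rB"
  cfg2 <- LandmarkConfig(specimenId(cfg), pts, coords(cfg))
  atlas <- suppressWarnings(buildAtlas(pyr$mesh, cfg2, pyr$curves))
  fixedLabels <- pts$label[pts$class != "surface"]

  spec <- makePyramid(
    base_depth = 1.2, height = 1.5,
    fossa = list(center = c(0.5, 0.35), radius = 0.14),
    mesh_resolution = 1000L, specimen_id = "spec"
  )
  specFixed <- fixedOnly(spec$config)
  resP <- piecemealPatch(
    list(rA = atlas, rB = atlas), spec$mesh, specFixed,
    anchor_regions = list(rB = fixedLabels)
  )
  expect_false(resP@failed)
  resG <- placePatch(atlas, spec$mesh, specFixed)
  surfLabels <- pts$label[surfIdx]
  expect_lt(
    max(abs(coords(resP@config)[surfLabels, ] - coords(resG@config)[surfLabels, ])),
    1e-9
  )
  expect_equal(sort(resP@diagnostics$label), sort(surfLabels))

  # duplicated region entries reuse the same surface labels
  expect_error(
    piecemealPatch(list(rA = atlas, rA = atlas), spec$mesh, specFixed),
    "overlapping surface-point labels"
  )

  # a failing region propagates as a failed value naming the region
  floating <- specFixed
  xyz <- coords(floating)
  xyz["apex", ] <- xyz["apex", ] + c(0, 0, 0.7)
  coords(floating) <- xyz
  resF <- piecemealPatch(
    list(rA = atlas, rB = atlas), spec$mesh, floating,
    anchor_regions = list(rB = fixedLabels)
  )
  expect_true(resF@failed)
  expect_match(resF@reason, "region 'rA'")
})
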