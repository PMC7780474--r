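# Configurations: CSV round trips, pts import, dropping, curve resampling,
# point allocation

test_that("configuration CSV round trip preserves everything", {
  pyr <- fixPyramid()
  p <- tempfile(fileext = ".csv")
  writeConfigurations(list(a = pyr$config), p)
  back <- readConfigurations(p)
  expect_equal(names(back), "pyramid")
  expect_equal(pointInfo(back$pyramid), pointInfo(pyr$config))
  expect_equal(coords(back$pyramid), coords(pyr$config))
})

test_that("mismatched point sets across specimens are reported by label", {
  pyr <- fixPyramid()
  c1 <- pyr$config
  c2 <- dropPoints(c1, "apex")
  c2@specimenId <- "other"
  p <- tempfile(fileext = ".csv")
  writeConfigurations(list(c1, c2), p)
  expect_error(readConfigurations(p), "apex")
  writeLines("specimen,label,x,y,z", p)
  expect_error(readConfigurations(p), "lacks columns")
})

test_that("readPts imports labelled landmarks and skips comments", {
  p <- tempfile(fileext = ".pts")
  writeLines(c("\"comment line", "# another", "lm1 0 0 0", "lm2 1.5 2 3"), p)
  cfg <- readPts(p)
  expect_equal(pointInfo(cfg)$label, c("lm1", "lm2"))
  expect_equal(unname(coords(cfg)[2, ]), c(1.5, 2, 3))
  expect_true(all(pointInfo(cfg)$class == "landmark"))
  writeLines("\"only comments", p)
  expect_error(readPts(p), "no point records")
})

test_that("dropPoints preserves order, renumbers ordinals, and validates", {
  pyr <- fixPyramid()
  cfg <- pyr$config
  victim <- pointInfo(cfg)$label[pointInfo(cfg)$curve_id %in% "edge_front"][2]
  out <- dropPoints(cfg, victim)
  expect_equal(nrow(coords(out)), nrow(coords(cfg)) - 1L)
  o <- pointInfo(out)
  sel <- o$curve_id %in% "edge_front"
  expect_equal(sort(o$ordinal[sel]), seq_len(sum(sel)) - 1L)
  expect_true(validObject(out))
  # survivors keep their original order
  expect_equal(o$label, setdiff(pointInfo(cfg)$label, victim))
  expect_error(dropPoints(cfg, "nonexistent"), "unknown labels")
  expect_error(dropPoints(cfg, pointInfo(cfg)$label), "empty configuration")
  # predicate form
  out2 <- dropPoints(cfg, function(p) p$class == "surface")
  expect_false(any(pointInfo(out2)$class == "surface"))
  expect_error(dropPoints(cfg, function(p) TRUE), "one logical per point")
})

test_that("resampleCurve matches the dense arc-length oracle", {
  set.seed(11)
  for (rep in 1:5) {
    poly <- apply(matrix(rnorm(3 * 8, sd = 0.3), 8, 3), 2, cumsum)
    n <- sample(4:40, 1)
    got <- resampleCurve(poly, n)
    want <- oracleResample(poly, n)
    expect_lt(max(abs(got - want)), 2e-3)
    # equal spacing along the polyline: consecutive chord lengths near-equal
    expect_equal(got[1, ], poly[1, ])
    expect_equal(got[n, ], poly[nrow(poly), ])
  }
})

test_that("resampleCurve on a straight segment is exactly uniform", {
  seg <- rbind(c(0, 0, 0), c(0.3, 0, 0), c(2, 0, 0))
  got <- resampleCurve(seg, 5)
  expect_equal(got[, 1], seq(0, 2, length.out = 5))
  expect_equal(got[, 2], rep(0, 5))
  expect_error(resampleCurve(seg[1, , drop = FALSE], 5), "at least 2")
  expect_error(resampleCurve(seg, 1), ">= 2")
  expect_error(resampleCurve(rbind(c(1, 1, 1), c(1, 1, 1)), 3), "zero-length")
})

test_that("allocateCurvePoints conserves the budget within bounds", {
  set.seed(3)
  for (rep in 1:20) {
    k <- sample(2:9, 1)
    lens <- runif(k, 0.1, 10)
    lo <- 5L
    hi <- 30L
    budget <- sample((k * lo):(k * hi), 1)
    n <- allocateCurvePoints(lens, budget, lo, hi)
    expect_equal(sum(n), budget)
    expect_true(all(n >= lo & n <= hi))
    # monotone in length when unclipped
    if (all(n > lo & n < hi)) {
      expect_true(all(diff(n[order(lens)]) >= -1L))
    }
  }
  expect_error(allocateCurvePoints(c(1, 1), 4), "infeasible")
  expect_error(allocateCurvePoints(c(1, 1), NULL), "either")
})

test_that("allocateCurvePoints spacing mode targets the requested density", {
  n <- allocateCurvePoints(c(10, 2), spacing = 1, min_per_curve = 2L)
  expect_equal(n, c(11L, 3L))
  n2 <- allocateCurvePoints(c(100, 0.1), spacing = 1)
  expect_equal(n2, c(30L, 5L)) # clipped to default bounds
  expect_error(allocateCurvePoints(1, spacing = 0), "positive")
})
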