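# Mirroring and the midline variance fraction

test_that("mirrorFill recovers a deleted side exactly on symmetric data", {
  bd <- makeBilateralDataset(
    n_specimens = 3, n_pairs = 9, noise_sd = 0, asymmetry_sd = 0, seed = 9
  )
  cfg <- bd$configs[[1]]
  truth <- coords(cfg)
  xyz <- truth
  xyz[bd$pairs[, 1], ] <- NA_real_
  broken <- cfg
  coords(broken) <- xyz
  fixed <- mirrorFill(broken, bd$pairs, bd$midline_labels)
  expect_lt(max(abs(coords(fixed) - truth)), 1e-12)
  # midline points stay fixed under the reflection
  expect_equal(coords(fixed)[bd$midline_labels, ], truth[bd$midline_labels, ])
  expect_equal(pointInfo(fixed), pointInfo(cfg))
})

test_that("imputed-vs-true RMS stays at the noise scale over 100 replicates", {
  noise <- 0.01
  rms <- vapply(1:100, function(s) {
    bd <- makeBilateralDataset(
      n_specimens = 2, n_pairs = 9, noise_sd = noise, mode_sd = 0, seed = s
    )
    cfg <- bd$configs[[1]]
    truth <- coords(cfg)
    xyz <- truth
    xyz[bd$pairs[, 1], ] <- NA_real_
    coords(cfg) <- xyz
    fixed <- mirrorFill(cfg, bd$pairs, bd$midline_labels)
    sqrt(mean((coords(fixed)[bd$pairs[, 1], ] - truth[bd$pairs[, 1], ])^2))
  }, 1)
  # reflection noise compounds digitizing noise of the source point and the
  # plane fit; stays within a factor 2 of the noise scale on average
  expect_lt(mean(rms), 2 * noise * sqrt(2))
  expect_gt(mean(rms), noise / 2)
})

test_that("mirrorFill error contract", {
  bd <- makeBilateralDataset(n_specimens = 2, n_pairs = 6, seed = 2)
  cfg <- bd$configs[[1]]
  # both sides present
  expect_error(mirrorFill(cfg, bd$pairs, bd$midline_labels), "exactly one present side")
  xyz <- coords(cfg)
  xyz[bd$pairs[, 1], ] <- NA_real_
  coords(cfg) <- xyz
  expect_error(mirrorFill(cfg, bd$pairs, bd$midline_labels[1:2]), "at least 3")
  # collinear midline
  xyz[bd$midline_labels, ] <- cbind(1:5, 0, 0)
  coords(cfg) <- xyz
  expect_error(mirrorFill(cfg, bd$pairs, bd$midline_labels), "collinear")
})

test_that("midlineVarianceFraction trivial cases", {
  set.seed(206)
  # all variance on the midline points, none elsewhere
  k <- 8
  base <- randomConfig(k)
  arr <- array(rep(base, 10), c(k, 3, 10))
  for (i in 1:10) arr[1:3, , i] <- arr[1:3, , i] + rnorm(9, sd = 0.05)
  dimnames(arr)[[1]] <- sprintf("p%d", 1:k)
  res <- gpa(arr)
  ml <- c("p1", "p2", "p3")
  expect_equal(midlineVarianceFraction(res, ml, reference_labels = ml), 1)
  frac <- midlineVarianceFraction(res, ml, reference_labels = sprintf("p%d", 1:k))
  expect_gte(frac, 0)
  expect_lte(frac, 1)
  # the rigid fit absorbs part of the noise (7 of 24 dof here) and spreads
  # it over all points, so the midline share drops well below 1
  expect_gt(frac, 0.6)
  # degenerate zero-variance dataset errors
  flatarr <- array(rep(base, 3), c(k, 3, 3))
  dimnames(flatarr)[[1]] <- sprintf("p%d", 1:k)
  res0 <- gpa(flatarr)
  expect_error(
    midlineVarianceFraction(res0, ml, reference_labels = sprintf("p%d", 4:8)),
    "zero variance"
  )
  expect_error(midlineVarianceFraction(res, character(0)), "empty")
  expect_error(midlineVarianceFraction(res, "nope"), "unknown midline")
})

test_that("bilateralVariant builds the four study designs", {
  bd <- makeBilateralDataset(n_specimens = 2, n_pairs = 9, seed = 3)
  cfg <- bd$configs[[1]]
  info <- pointInfo(cfg)
  v1 <- bilateralVariant(cfg, bd$pairs, bd$midline_labels, "one_sided")
  expect_false(any(pointInfo(v1)$side == "left"))
  v2 <- bilateralVariant(cfg, bd$pairs, bd$midline_labels, "left_landmarks")
  i2 <- pointInfo(v2)
  expect_true(all(i2$class[i2$side == "left"] == "landmark"))
  expect_equal(coords(v2)[i2$label[i2$side == "left"], ],
    coords(cfg)[i2$label[i2$side == "left"], ]) # digitized, not mirrored
  v3 <- bilateralVariant(cfg, bd$pairs, bd$midline_labels, "mirrored_curves")
  i3 <- pointInfo(v3)
  expect_setequal(unique(i3$class[i3$side == "left"]), c("landmark", "curve"))
  v4 <- bilateralVariant(cfg, bd$pairs, bd$midline_labels, "full_mirror")
  expect_equal(nrow(coords(v4)), nrow(coords(cfg)))
  # mirrored coords differ from digitized ones (noise) but only slightly
  lsurf <- pointInfo(v4)$label[pointInfo(v4)$side == "left" &
    pointInfo(v4)$class == "surface"]
  expect_gt(max(abs(coords(v4)[lsurf, ] - coords(cfg)[lsurf, ])), 0)
  expect_lt(max(abs(coords(v4)[lsurf, ] - coords(cfg)[lsurf, ])), 0.2)
})
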