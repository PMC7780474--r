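# Sampling curves, dataset fit, random skewers

evalFixture <- function() {
  cached("eval_alignments", function() {
    bdA <- semiland::makeBilateralDataset(
      n_specimens = 12, n_pairs = 6, noise_sd = 0.01, seed = 41
    )
    # second digitization of the same specimens: same generator, extra noise
    bdB <- bdA
    bdB$configs <- lapply(bdA$configs, function(cfg) {
      xyz <- semiland::coords(cfg)
      semiland::coords(cfg) <- xyz + matrix(rnorm(length(xyz), sd = 0.005), nrow(xyz), 3)
      cfg
    })
    set.seed(42)
    list(a = semiland::gpa(bdA$configs), b = semiland::gpa(bdB$configs))
  })
}

test_that("sampling-curve fit at k = n is exactly 1", {
  fx <- evalFixture()
  K <- dim(alignedArray(fx$a))[1]
  sc <- samplingCurve(fx$a, iterations = 3L, k_values = K)
  expect_equal(max(abs(sc$fits - 1)), 0, tolerance = 1e-10)
  expect_equal(unname(sc$k_at_fit["0.99"]), K)
})

test_that("sampling curve rises toward 1 and reports threshold sizes", {
  fx <- evalFixture()
  K <- dim(alignedArray(fx$a))[1]
  sc <- samplingCurve(fx$a, iterations = 8L, k_values = c(3L, 6L, 10L, K))
  expect_true(all(sc$fits >= 0 & sc$fits <= 1 + 1e-12))
  expect_equal(sc$median_fit[length(sc$median_fit)], 1, tolerance = 1e-10)
  expect_gt(sc$median_fit[length(sc$median_fit)], sc$median_fit[1])
  expect_true(all(sc$q05 <= sc$median_fit + 1e-12))
  expect_output(print(sc), "samplingCurve")
  # cheap non-realigned variant also ends at 1
  sc2 <- samplingCurve(fx$a, iterations = 3L, k_values = K, realign = FALSE)
  expect_equal(sc2$median_fit, 1, tolerance = 1e-10)
  expect_error(samplingCurve(fx$a, iterations = 0L), ">= 1")
  tiny <- gpa(array(rnorm(3 * 3 * 4), c(3, 3, 4),
    dimnames = list(c("a", "b", "c"), NULL, sprintf("s%d", 1:4))
  ))
  expect_error(samplingCurve(tiny), "at least 4 points")
})

test_that("writeSamplingCurve emits CSV and JSON", {
  fx <- evalFixture()
  K <- dim(alignedArray(fx$a))[1]
  sc <- samplingCurve(fx$a, iterations = 3L, k_values = c(5L, K))
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  writeSamplingCurve(sc, csv, js)
  tab <- read.csv(csv)
  expect_equal(names(tab), c("k", "median_fit", "q05", "q95"))
  expect_equal(tab$k, c(5L, K))
  parsed <- jsonlite::read_json(js)
  expect_named(parsed, "k_at_fit")
})

test_that("fitBetweenDatasets matches an established PROTEST implementation", {
  fx <- evalFixture()
  res <- fitBetweenDatasets(fx$a, fx$b, permutations = 199L)
  expect_gt(res$fit, 0.8) # same specimens, mild re-digitization noise
  expect_lt(res$p_value, 0.05)
  # independent oracle: vegan's protest statistic t0
  ia <- dimnames(alignedArray(fx$a))[[3]]
  ib <- dimnames(alignedArray(fx$b))[[3]]
  X <- pcaScores(fx$a)
  Y <- pcaScores(fx$b)[match(ia, ib), , drop = FALSE]
  t0 <- suppressWarnings(vegan::protest(X, Y, permutations = 29)$t0)
  expect_equal(res$fit, unname(t0), tolerance = 1e-8)
  # self-fit is exactly 1 with the smallest possible p-value
  self <- fitBetweenDatasets(fx$a, fx$a, permutations = 99L)
  expect_equal(self$fit, 1, tolerance = 1e-12)
  expect_equal(self$p_value, 1 / 100)
  # specimen mismatch errors
  sub <- gpa(alignedArray(fx$a)[, , 1:8])
  expect_error(fitBetweenDatasets(fx$a, sub), "different specimens")
})

test_that("random skewers of a matrix with itself is exactly 1", {
  set.seed(77)
  M <- matrix(rnorm(100), 20, 5)
  A <- crossprod(M)
  rs <- randomSkewers(A, A, n_iterations = 500L)
  expect_equal(rs$correspondence, 1, tolerance = 1e-12)
  # scale invariance: proportional matrices respond identically in direction
  expect_equal(randomSkewers(A, 3.7 * A, n_iterations = 500L)$correspondence, 1,
    tolerance = 1e-12
  )
  expect_lt(rs$p_value, 0.01)
  expect_output(print(rs), "randomSkewers")
  expect_error(randomSkewers(A, diag(4)), "differ in dimension")
  # unrelated high-dimensional covariances have low correspondence
  set.seed(78)
  B <- crossprod(matrix(rnorm(100), 20, 5))
  rs2 <- randomSkewers(A, B, n_iterations = 2000L)
  expect_lt(rs2$correspondence, 0.9)
})

test_that("traitCovariance has 3k dimensions and is PSD", {
  fx <- evalFixture()
  k <- dim(alignedArray(fx$a))[1]
  V <- traitCovariance(fx$a)
  expect_equal(dim(V), c(3 * k, 3 * k))
  expect_equal(V, t(V))
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10 * max(ev))
})
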