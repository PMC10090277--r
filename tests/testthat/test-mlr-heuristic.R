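test_that("fitOLS reproduces hand-computed lines and statistics", {
  # exact line through the origin-ish points
  m <- fitOLS(matrix(1:3, dimnames = list(NULL, "x")), c(2, 4, 6))
  expect_equal(m@intercept, 0, tolerance = 1e-12)
  expect_equal(unname(m@coefficients), 2, tolerance = 1e-12)
  expect_equal(m@r2, 1, tolerance = 1e-12)
  # hand OLS via covariance formulas: slope 1.5, intercept -2/3, R2 = 27/28
  m2 <- fitOLS(matrix(1:3, dimnames = list(NULL, "x")), c(1, 2, 4))
  expect_equal(unname(m2@coefficients), 1.5, tolerance = 1e-12)
  expect_equal(m2@intercept, -2 / 3, tolerance = 1e-12)
  expect_equal(m2@r2, 27 / 28, tolerance = 1e-12)
})

test_that("fitOLS rejects rank-deficient designs, naming a dependent column", {
  X <- cbind(a = rnorm(10), b = rnorm(10))
  X <- cbind(X, c = X[, "a"])
  expect_error(fitOLS(X, rnorm(10)), "c")
  expect_error(fitOLS(matrix(rnorm(4), 2, 2), rnorm(2)), "rows")
})

test_that("LOO r2cv equals the brute-force refit oracle", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(10:30, 1); p <- sample(1:5, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("v", 1:p)))
    y <- rnorm(n)
    m <- fitOLS(X, y)
    expect_equal(m@r2cv, looCv(X, y, fitOLS), tolerance = 1e-10)
    expect_gte(m@r2, m@r2cv)
  }
})

test_that("descriptorCorrelation gives Pearson with unit diagonal", {
  # zero cross-moment by hand
  X <- cbind(u = c(1, -1, 0), v = c(1, 1, -2))
  cm <- descriptorCorrelation(X)
  expect_equal(cm["u", "v"], 0, tolerance = 1e-12)
  expect_equal(diag(cm), c(u = 1, v = 1))
  # identical columns correlate exactly 1
  X2 <- cbind(a = rnorm(8))
  X2 <- cbind(X2, b = X2[, "a"])
  expect_equal(descriptorCorrelation(X2)["a", "b"], 1, tolerance = 1e-12)
  expect_error(descriptorCorrelation(cbind(a = rnorm(5), k = rep(2, 5))),
               "k")
})

test_that("noise-free planted subsets are recovered exactly", {
  set.seed(2)
  X <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(NULL, paste0("x", 0:7)))
  y <- 3 * X[, "x0"] - 2 * X[, "x3"]
  trace <- heuristicSearch(X, y, maxSize = 4)
  m <- chosenModel(trace, 2)
  expect_setequal(names(m@coefficients), c("x0", "x3"))
  expect_equal(m@r2, 1, tolerance = 1e-10)
  expect_equal(trace@chosenSize, 2L)
})

test_that("best two-descriptor model matches exhaustive pair search", {
  hits <- 0L
  for (s in 1:8) {
    d <- genDescriptorTable(syntheticSpec(seed = s, n = 40, p = 10,
                                          plantedSubset = c(2, 7),
                                          beta = c(2, -1.5), noiseSD = 0.15))
    X <- descriptorValues(d$descriptors)
    trace <- heuristicSearch(X, d$activities, maxSize = 3, fFloor = 0)
    best2 <- sort(names(chosenModel(trace, 2)@coefficients))
    pairs <- combn(colnames(X), 2)
    r2s <- apply(pairs, 2, function(p) fitOLS(X[, p], d$activities)@r2)
    if (identical(best2, sort(pairs[, which.max(r2s)]))) hits <- hits + 1L
  }
  expect_gte(hits, 7L)
})

test_that("search respects the collinearity cap and R2 grows with size", {
  d <- genDescriptorTable(syntheticSpec(seed = 13, n = 60, p = 20,
                                        plantedSubset = c(1, 5, 9),
                                        beta = c(3, -2, 1.5), noiseSD = 0.2,
                                        corBlockSize = 6, corRho = 0.7))
  X <- descriptorValues(d$descriptors)
  trace <- heuristicSearch(X, d$activities, maxSize = 6,
                           collinearityMax = 0.8)
  expect_true(all(diff(trace@sizeStats$r2) >= -1e-12))
  for (m in trace@bestPerSize) {
    vars <- names(m@coefficients)
    if (length(vars) > 1) {
      cm <- descriptorCorrelation(X[, vars])
      expect_lt(max(abs(cm[upper.tri(cm)])), 0.8)
    }
  }
  cm <- trace@correlationMatrix
  expect_equal(unname(diag(cm)), rep(1, nrow(cm)))
})

test_that("search truncates with a warning when nothing can be added", {
  set.seed(4)
  a <- rnorm(20)
  X <- cbind(a = a, b = a + rnorm(20, sd = 0.05))  # |r| > 0.8 by design
  y <- a + rnorm(20, sd = 0.1)
  expect_gt(abs(descriptorCorrelation(X)["a", "b"]), 0.8)
  expect_warning(trace <- heuristicSearch(X, y, maxSize = 2),
                 "truncated")
  expect_length(trace@bestPerSize, 1L)
})
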