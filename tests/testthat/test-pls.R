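test_that("one-component PLS on a single column equals OLS", {
  set.seed(41)
  for (i in 1:5) {
    X <- matrix(rnorm(15), 15, 1, dimnames = list(NULL, "x"))
    y <- 2 * X[, 1] + rnorm(15)
    m <- plsFit(X, y, 1)
    ols <- fitOLS(X, y)
    expect_equal(predict(m, X), predict(ols, X), tolerance = 1e-10)
  }
})

test_that("full-rank PLS predictions equal multi-column OLS", {
  set.seed(43)
  for (i in 1:5) {
    n <- sample(12:25, 1); p <- sample(2:6, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
    y <- rnorm(n)
    m <- plsFit(X, y, p)
    ols <- fitOLS(X, y)
    expect_equal(predict(m, X), unname(predict(ols, X)), tolerance = 1e-8)
  }
})

test_that("constant response predicts itself and degenerate args error", {
  X <- matrix(rnorm(20), 10, 2)
  m <- plsFit(X, rep(3.5, 10), 1)
  expect_equal(predict(m, X), rep(3.5, 10), tolerance = 1e-12)
  expect_error(plsFit(X, rnorm(10), 0), "ncomp")
  expect_error(plsFit(X, rnorm(10), 5), "ncomp")
})

test_that("predictions are invariant to column centering constants", {
  set.seed(47)
  X <- matrix(rnorm(18 * 4), 18, 4)
  y <- X[, 1] - 0.5 * X[, 3] + rnorm(18, sd = 0.2)
  m1 <- plsFit(X, y, 2)
  shift <- matrix(rep(c(10, -5, 100, 0.3), each = 18), 18, 4)
  m2 <- plsFit(X + shift, y, 2)
  expect_equal(predict(m1, X), predict(m2, X + shift), tolerance = 1e-8)
})

test_that("LOO component selection matches the brute-force oracle", {
  set.seed(53)
  for (i in 1:5) {
    n <- sample(10:20, 1); p <- sample(3:8, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- X[, 1] + rnorm(n, sd = 0.5)
    m <- plsLooOnc(X, y, maxComp = 5)
    oracle <- looCv(X, y, function(Xi, yi) plsFit(Xi, yi, m@ncomp))
    expect_equal(m@q2, oracle, tolerance = 1e-10)
  }
})

test_that("a single noise-free latent direction gives Q2 ~ 1 at one component", {
  set.seed(59)
  t <- rnorm(20)
  X <- outer(t, runif(12, -1, 1))          # rank-1 design
  X <- X + matrix(rnorm(240, sd = 1e-6), 20, 12)
  y <- 2 * t + 1
  m <- plsLooOnc(X, y, maxComp = 5)
  expect_equal(m@ncomp, 1L)
  expect_gte(m@q2, 0.99)
})

test_that("permuted responses rarely cross the robustness threshold", {
  set.seed(61)
  X <- matrix(rnorm(20 * 10), 20, 10)
  y <- X[, 1] + rnorm(20, sd = 0.2)
  low <- 0L
  for (s in 1:10) {
    set.seed(100 + s)
    m <- plsLooOnc(X, sample(y), maxComp = 5)
    if (m@q2 <= 0.2) low <- low + 1L
  }
  expect_gte(low, 9L)
})

test_that("SEE and F follow the stated degrees of freedom", {
  set.seed(67)
  X <- matrix(rnorm(16 * 3), 16, 3)
  y <- X %*% c(1, -2, 0.5) + rnorm(16, sd = 0.3)
  m <- plsFit(X, y, 2)
  pred <- predict(m, X)
  rss <- sum((y - pred)^2)
  expect_equal(m@see, sqrt(rss / (16 - 2 - 1)), tolerance = 1e-10)
  expect_equal(m@fStat, (m@r2 / 2) / ((1 - m@r2) / (16 - 2 - 1)),
               tolerance = 1e-10)
})

test_that("pretreatment screens flat columns and balances field blocks", {
  g <- genAlignedMolecules(syntheticSpec(seed = 5, n = 12, noiseSD = 0))
  raw <- comsiaFieldMatrix(g$molecules)
  ft <- comsiaPretreat(raw)
  expect_true(ft@scaled)
  expect_lt(ncol(ft@values), ncol(raw@values))  # scaffold columns are flat
  for (f in unique(ft@fieldLabels)) {
    tot <- sum(apply(ft@values[, ft@fieldLabels == f, drop = FALSE], 2, var))
    expect_equal(tot, 1, tolerance = 1e-9)
  }
  expect_identical(comsiaPretreat(ft), ft)  # idempotent
})

test_that("contours score columns by coeff x sd and fractions sum to one", {
  g <- genAlignedMolecules(syntheticSpec(seed = 7, n = 15, noiseSD = 0.05))
  fit <- comsiaPLS(comsiaFieldMatrix(g$molecules), g$activities)
  fr <- fieldFractions(fit$model)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  expect_true(all(fr >= 0))
  lv <- fit$contours@levels
  ok <- !is.na(lv$favLevel) & !is.na(lv$unfavLevel)
  expect_true(all(lv$favLevel[ok] >= lv$unfavLevel[ok]))
  # a model with coefficients confined to one field puts fraction 1 there
  ft <- fit$fields
  mono <- fit$model
  mono@coefficients[ft@fieldLabels != "S"] <- 0
  cs <- contourAndContrib(mono, ft)
  expect_equal(unname(fieldFractions(cs)["S"]), 1, tolerance = 1e-12)
  expect_true(all(fieldFractions(cs)[names(fieldFractions(cs)) != "S"] == 0))
})

test_that("planted electrostatic effects surface as the top field", {
  rank1 <- 0L
  for (s in 1:4) {
    g <- genAlignedMolecules(syntheticSpec(seed = s, n = 20, noiseSD = 0.05))
    fit <- comsiaPLS(comsiaFieldMatrix(g$molecules), g$activities)
    if (names(which.max(fieldFractions(fit$model))) == "E") rank1 <- rank1 + 1L
  }
  expect_gte(rank1, 3L)
})
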