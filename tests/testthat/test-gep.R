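fs4 <- defaultFunctionSet(4)

test_that("Karva decoding matches hand-constructed expression trees", {
  for (case in karvaCases()) {
    g <- karvaGene(case$sym, case$h, fs4)
    tree <- decodeKarva(g, fs4)
    expect_identical(treeToInfix(tree), case$infix)
    val <- evaluateTree(tree, case$at)
    if (is.na(case$value)) expect_true(is.na(val))
    else expect_equal(unname(val), case$value, tolerance = 1e-12)
  }
})

test_that("gene construction enforces head/tail structure", {
  # tail length for h = 2, max arity 2 is 3; total 5
  expect_equal(karvaTailLength(2, fs4), 3L)
  expect_error(karvaGene(c("+", "X0", "X1", "+", "X2"), 2, fs4), "tail")
  expect_error(karvaGene(c("+", "X0", "X1"), 2, fs4), "length")
  expect_error(karvaGene(c("+", "X0", "X1", "X2", "q"), 2, fs4), "unknown")
})

test_that("arithmetic guards return the invalid marker, never an exception", {
  tree <- decodeKarva(karvaGene(c("Ln", "X0", "X0"), 1, fs4), fs4)
  expect_equal(unname(evaluateTree(tree, c(X0 = exp(1)))), 1,
               tolerance = 1e-12)
  expect_true(is.na(evaluateTree(tree, c(X0 = 0))))
  expect_true(is.na(evaluateTree(tree, c(X0 = -2))))
  div <- decodeKarva(karvaGene(c("/", "X0", "X1", "X0", "X0"), 2, fs4), fs4)
  expect_true(is.na(evaluateTree(div, c(X0 = 1, X1 = 0))))
  expect_true(is.na(evaluateTree(div, c(X0 = 1, X1 = 1e-13))))
  # vectorized evaluation marks only the offending rows
  X <- cbind(X0 = c(1, 2), X1 = c(0, 2))
  expect_equal(is.na(evaluateTree(div, X)), c(TRUE, FALSE))
  expect_error(evaluateTree(div, c(X9 = 1)), "unbound")
})

test_that("fitness is R2 floored at zero with invalids scoring 0", {
  set.seed(31)
  X <- cbind(X0 = rnorm(20), X1 = rnorm(20), X2 = rep(0, 20))
  fs <- defaultFunctionSet(3)
  # single-gene chromosome computing X0 exactly
  chrExact <- new("Chromosome",
                  genes = list(karvaGene(c("X0", "X0", "X0"), 1, fs)))
  expect_equal(fitnessR2(chrExact, X, X[, "X0"], fs), 1, tolerance = 1e-12)
  # predicting a constant: SSres = SStot at the mean, fitness floored to 0
  y <- rnorm(20)
  chrConst <- new("Chromosome",
                  genes = list(karvaGene(c("-", "X0", "X0", "X0", "X0"),
                                         2, fs)))
  expect_equal(fitnessR2(chrConst, X, y - mean(y), fs), 0)
  # division by an all-zero column invalidates the chromosome
  chrDiv <- new("Chromosome",
                genes = list(karvaGene(c("/", "X0", "X2", "X0", "X0"),
                                       2, fs)))
  expect_equal(fitnessR2(chrDiv, X, y, fs), 0)
})

test_that("decode -> encode round-trip preserves semantics", {
  set.seed(17)
  fs <- defaultFunctionSet(3)
  X <- cbind(X0 = runif(25, 0.5, 2), X1 = runif(25, 0.5, 2),
             X2 = runif(25, 0.5, 2))
  for (i in 1:25) {
    g <- mustardQSAR:::randomGene(fs, 5L)
    tree <- decodeKarva(g, fs)
    g2 <- encodeKarva(tree, fs, 8L)
    tree2 <- decodeKarva(g2, fs)
    v1 <- evaluateTree(tree, X)
    v2 <- evaluateTree(tree2, X)
    expect_equal(v1, v2, tolerance = 1e-12)
  }
})

test_that("genetic operators always produce structurally valid genes", {
  set.seed(23)
  fs <- defaultFunctionSet(4)
  cfg <- new("GEPConfig", h = 6L, nGenes = 3L)
  fnNames <- names(fs@ops)
  checkValid <- function(chr) {
    for (g in chr@genes) {
      tail <- g@symbols[(g@h + 1L):length(g@symbols)]
      expect_false(any(tail %in% fnNames))
      expect_length(g@symbols, g@h + karvaTailLength(g@h, fs))
    }
  }
  for (i in 1:40) {
    a <- mustardQSAR:::randomChromosome(fs, cfg)
    b <- mustardQSAR:::randomChromosome(fs, cfg)
    a <- mustardQSAR:::opMutate(a, 0.5, fs)
    a <- mustardQSAR:::opInversion(a, 1)
    a <- mustardQSAR:::opIsTransposition(a, 1)
    a <- mustardQSAR:::opRisTransposition(a, 1, fs)
    a <- mustardQSAR:::opGeneTransposition(a, 1)
    pair <- mustardQSAR:::opOnePoint(a, b, 1)
    pair <- mustardQSAR:::opTwoPoint(pair[[1]], pair[[2]], 1)
    pair <- mustardQSAR:::opGeneRecombination(pair[[1]], pair[[2]], 1)
    checkValid(pair[[1]])
    checkValid(pair[[2]])
  }
})

test_that("evolution is elitist, seeded, and size-preserving", {
  d <- genSymbolicDataset(syntheticSpec(seed = 3, n = 40, p = 3,
                                        expressionId = "f1", noiseSD = 0.1))
  cfg <- new("GEPConfig", seed = 7L, populationSize = 30L,
             maxGenerations = 25L)
  r1 <- evolveGEP(d$X, d$y, config = cfg)
  r2 <- evolveGEP(d$X, d$y, config = cfg)
  expect_identical(r1, r2)  # same seed, bit-identical result
  expect_true(all(diff(r1@fitnessHistory) >= 0))  # best-so-far monotone
  # all rates zero + elitism: best fitness never moves
  zero <- cfg
  zero@rates[] <- 0
  zero@maxGenerations <- 15L
  r0 <- evolveGEP(d$X, d$y, config = zero)
  expect_equal(length(unique(r0@fitnessHistory)), 1L)
})

test_that("evolution recovers an identity target exactly at zero noise", {
  set.seed(101)
  X <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, paste0("X", 0:2)))
  y <- X[, "X0"]
  reached <- FALSE
  for (s in 0:4) {
    cfg <- new("GEPConfig", seed = as.integer(s), maxGenerations = 50L)
    res <- evolveGEP(X, y, config = cfg)
    if (!is.na(res@trainR2) && res@trainR2 >= 1 - 1e-9) { reached <- TRUE; break }
  }
  expect_true(reached)
})
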