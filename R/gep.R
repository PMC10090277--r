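## Gene expression programming: fixed-length linear genomes in Karva
## notation, decoded breadth-first into expression trees, evolved under the
## classical operator schedule with roulette-wheel selection and one cloned
## elite. Arithmetic never raises: division by (near-)zero, logs of
## non-positive arguments and overflow all yield an invalid marker (NA) that
## zeroes the chromosome's fitness.

DIV_EPS <- 1e-12

#' The default symbolic-regression function set
#'
#' Operators: `+ - * /` (binary) and `Ln`, `sin` (unary); terminals
#' `X0 ... X(p-1)` mapped to descriptor columns.
#'
#' @param nTerminals number of terminal symbols.
#' @return a [FunctionSet-class].
#' @export
defaultFunctionSet <- function(nTerminals) {
  stopifnot(nTerminals >= 1)
  new("FunctionSet",
      ops = list(
        "+"   = list(arity = 2),
        "-"   = list(arity = 2),
        "*"   = list(arity = 2),
        "/"   = list(arity = 2),
        "Ln"  = list(arity = 1),
        "sin" = list(arity = 1)),
      terminals = paste0("X", seq_len(nTerminals) - 1L))
}

fsetArity <- function(fset) {
  vapply(fset@ops, function(o) as.integer(o$arity), integer(1))
}

maxArity <- function(fset) max(fsetArity(fset))

#' Tail length of a Karva gene
#' @param h head length
#' @param fset a [FunctionSet-class]
#' @return integer tail length `h * (maxArity - 1) + 1`
#' @export
karvaTailLength <- function(h, fset) h * (maxArity(fset) - 1L) + 1L

#' Construct a Karva gene, enforcing the head/tail constraint
#'
#' @param symbols character vector of length `h + tail`; the first `h`
#'   positions may hold functions or terminals, the rest terminals only.
#' @param h head length.
#' @param fset the [FunctionSet-class] the symbols are drawn from.
#' @return a [Gene-class].
#' @export
karvaGene <- function(symbols, h, fset) {
  h <- as.integer(h)
  t <- karvaTailLength(h, fset)
  if (length(symbols) != h + t)
    stop("gene must have length h + t = ", h + t)
  known <- c(names(fset@ops), fset@terminals)
  if (!all(symbols %in% known))
    stop("unknown symbol: ", setdiff(symbols, known)[1L])
  tail <- symbols[(h + 1L):(h + t)]
  if (any(tail %in% names(fset@ops)))
    stop("function symbol in tail: ",
         tail[tail %in% names(fset@ops)][1L])
  new("Gene", symbols = as.character(symbols), h = h)
}

randomGene <- function(fset, h) {
  t <- karvaTailLength(h, fset)
  headPool <- c(names(fset@ops), fset@terminals)
  new("Gene",
      symbols = c(sample(headPool, h, replace = TRUE),
                  sample(fset@terminals, t, replace = TRUE)),
      h = as.integer(h))
}

#' Decode a Karva gene into an expression tree
#'
#' Breadth-first reading: symbol 1 is the root; each function node consumes
#' the next unused symbols left to right, level by level; trailing unused
#' symbols are ignored (they are the gene's silent region).
#'
#' @param gene a [Gene-class].
#' @param fset the [FunctionSet-class].
#' @return a `karvaTree`: list with `sym` (symbol per node), `kids` (integer
#'   child indices per node) and `nUsed` (symbols consumed).
#' @export
decodeKarva <- function(gene, fset) {
  syms <- gene@symbols
  arities <- fsetArity(fset)
  sym <- character(0)
  kids <- list()
  sym[1L] <- syms[1L]
  kids[[1L]] <- integer(0)
  queue <- 1L
  nxt <- 2L
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    a <- arities[sym[i]]
    if (is.na(a)) next  # terminal
    if (nxt + a - 1L > length(syms))
      stop("gene too short to decode (function symbol in tail?)")
    ch <- nxt:(nxt + a - 1L)
    for (j in ch) { sym[j] <- syms[j]; kids[[j]] <- integer(0) }
    kids[[i]] <- ch
    queue <- c(queue, ch)
    nxt <- nxt + a
  }
  structure(list(sym = sym, kids = kids, nUsed = nxt - 1L),
            class = "karvaTree")
}

#' Re-encode an expression tree as a Karva gene
#'
#' Lists the tree's symbols in breadth-first order and pads the remainder
#' with terminals. Fails if a function symbol would land in the tail, i.e.
#' the tree is too deep for the requested head length.
#'
#' @param tree a `karvaTree`.
#' @param fset the [FunctionSet-class].
#' @param h head length of the target gene.
#' @return a [Gene-class] whose decoding has the same semantics as `tree`.
#' @export
encodeKarva <- function(tree, fset, h) {
  bfs <- integer(0)
  queue <- 1L
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    bfs <- c(bfs, i)
    queue <- c(queue, tree$kids[[i]])
  }
  syms <- tree$sym[bfs]
  t <- karvaTailLength(h, fset)
  if (length(syms) > h + t)
    stop("tree needs ", length(syms), " symbols; gene holds ", h + t)
  isFn <- syms %in% names(fset@ops)
  if (any(isFn & seq_along(syms) > h))
    stop("tree too deep: function symbol would fall in the tail; increase h")
  pad <- rep(fset@terminals[1L], h + t - length(syms))
  karvaGene(c(syms, pad), h, fset)
}

#' Evaluate an expression tree on terminal values
#'
#' Arithmetic is total by design: division with |denominator| < 1e-12,
#' `Ln` of a non-positive argument, and any non-finite intermediate all
#' produce the invalid marker `NA` instead of raising.
#'
#' @param tree a `karvaTree` from [decodeKarva()].
#' @param X numeric matrix whose columns are named by terminal symbols, or a
#'   single named vector (one row).
#' @return numeric vector, one value per row of `X`; `NA` marks invalid rows.
#' @export
evaluateTree <- function(tree, X) {
  if (is.null(dim(X))) X <- matrix(X, 1L, dimnames = list(NULL, names(X)))
  evalNode <- function(i) {
    s <- tree$sym[i]
    ch <- tree$kids[[i]]
    if (!length(ch)) {
      if (!s %in% colnames(X)) stop("unbound terminal: ", s)
      return(X[, s])
    }
    a <- evalNode(ch[1L])
    v <- switch(s,
      "+" = a + evalNode(ch[2L]),
      "-" = a - evalNode(ch[2L]),
      "*" = a * evalNode(ch[2L]),
      "/" = {
        b <- evalNode(ch[2L])
        out <- a / b
        out[abs(b) < DIV_EPS] <- NA_real_
        out
      },
      "Ln" = {
        out <- suppressWarnings(log(a))
        out[a <= 0] <- NA_real_
        out
      },
      "sin" = sin(a),
      stop("unknown operator: ", s))
    v[!is.finite(v)] <- NA_real_
    v
  }
  evalNode(1L)
}

#' Infix rendering of an expression tree
#' @param tree a `karvaTree`
#' @return a printable infix string (fully parenthesized)
#' @export
treeToInfix <- function(tree) {
  render <- function(i) {
    s <- tree$sym[i]
    ch <- tree$kids[[i]]
    if (!length(ch)) return(s)
    if (length(ch) == 1L) return(paste0(s, "(", render(ch[1L]), ")"))
    paste0("(", render(ch[1L]), s, render(ch[2L]), ")")
  }
  render(1L)
}

randomChromosome <- function(fset, config) {
  new("Chromosome",
      genes = replicate(config@nGenes, randomGene(fset, config@h),
                        simplify = FALSE),
      linking = "+")
}

#' Predictions of a multigenic chromosome
#'
#' Gene sub-expressions are combined with the linking operator (default
#' `+`). Invalid markers propagate.
#'
#' @param chromosome a [Chromosome-class].
#' @param X numeric matrix with terminal-named columns.
#' @param fset the [FunctionSet-class].
#' @return numeric predictions, `NA` where any gene is invalid.
#' @export
chromosomePredict <- function(chromosome, X, fset) {
  vals <- lapply(chromosome@genes,
                 function(g) evaluateTree(decodeKarva(g, fset), X))
  out <- vals[[1L]]
  link <- chromosome@linking
  for (v in vals[-1L]) {
    out <- switch(link, "+" = out + v, "*" = out * v,
                  stop("unsupported linking operator: ", link))
  }
  out[!is.finite(out)] <- NA_real_
  out
}

#' Infix rendering of a chromosome
#' @param chromosome a [Chromosome-class]
#' @param fset the [FunctionSet-class]
#' @return infix string with genes joined by the linking operator
#' @export
chromosomeToInfix <- function(chromosome, fset) {
  paste(vapply(chromosome@genes,
               function(g) treeToInfix(decodeKarva(g, fset)), character(1)),
        collapse = paste0(" ", chromosome@linking, " "))
}

#' R2 fitness of a chromosome
#'
#' Coefficient of determination of the chromosome's raw predictions against
#' `y`, floored at 0 so selection weights stay non-negative; any invalid
#' evaluation on any row gives fitness 0. A total function by design.
#'
#' @param chromosome a [Chromosome-class].
#' @param X numeric matrix with terminal-named columns.
#' @param y numeric response.
#' @param fset the [FunctionSet-class].
#' @return fitness in `[0, 1]`.
#' @export
fitnessR2 <- function(chromosome, X, y, fset) {
  pred <- chromosomePredict(chromosome, X, fset)
  if (anyNA(pred)) return(0)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(0)
  max(0, 1 - sum((y - pred)^2) / sst)
}

## ---- genetic operators -----------------------------------------------------
## All operators preserve the head/tail constraint by construction: head
## positions may receive any symbol, tail positions only terminals, and
## recombination exchanges aligned regions of identically-structured genomes.

opMutate <- function(chr, rate, fset) {
  headPool <- c(names(fset@ops), fset@terminals)
  for (k in seq_along(chr@genes)) {
    g <- chr@genes[[k]]
    L <- length(g@symbols)
    hit <- which(stats::runif(L) < rate)
    for (i in hit) {
      g@symbols[i] <- if (i <= g@h) sample(headPool, 1L)
                      else sample(fset@terminals, 1L)
    }
    chr@genes[[k]] <- g
  }
  chr
}

opInversion <- function(chr, rate) {
  if (stats::runif(1) >= rate) return(chr)
  k <- sample.int(length(chr@genes), 1L)
  g <- chr@genes[[k]]
  if (g@h < 2L) return(chr)
  pts <- sort(sample.int(g@h, 2L))
  g@symbols[pts[1L]:pts[2L]] <- rev(g@symbols[pts[1L]:pts[2L]])
  chr@genes[[k]] <- g
  chr
}

## insertion-sequence transposition: a short segment from anywhere in the
## genome is copied into a non-root head position; overflow is truncated.
opIsTransposition <- function(chr, rate) {
  if (stats::runif(1) >= rate) return(chr)
  src <- chr@genes[[sample.int(length(chr@genes), 1L)]]@symbols
  len <- sample.int(3L, 1L)
  start <- sample.int(length(src) - len + 1L, 1L)
  seg <- src[start:(start + len - 1L)]
  k <- sample.int(length(chr@genes), 1L)
  g <- chr@genes[[k]]
  if (g@h < 2L) return(chr)
  at <- sample(2:g@h, 1L)
  head <- g@symbols[1:g@h]
  head <- append(head, seg, after = at - 1L)[1:g@h]
  g@symbols[1:g@h] <- head
  chr@genes[[k]] <- g
  chr
}

## root-insertion-sequence transposition: a segment starting at a function
## symbol in the head becomes the new gene root.
opRisTransposition <- function(chr, rate, fset) {
  if (stats::runif(1) >= rate) return(chr)
  k <- sample.int(length(chr@genes), 1L)
  g <- chr@genes[[k]]
  scanFrom <- sample.int(g@h, 1L)
  headSyms <- g@symbols[1:g@h]
  fnAt <- which(headSyms %in% names(fset@ops))
  fnAt <- fnAt[fnAt >= scanFrom]
  if (!length(fnAt)) return(chr)
  start <- fnAt[1L]
  len <- min(sample.int(3L, 1L), g@h - start + 1L)
  seg <- headSyms[start:(start + len - 1L)]
  g@symbols[1:g@h] <- c(seg, headSyms)[1:g@h]
  chr@genes[[k]] <- g
  chr
}

opGeneTransposition <- function(chr, rate) {
  if (length(chr@genes) < 2L || stats::runif(1) >= rate) return(chr)
  k <- sample(2:length(chr@genes), 1L)
  chr@genes <- c(chr@genes[k], chr@genes[-k])
  chr
}

flattenChr <- function(chr) unlist(lapply(chr@genes, function(g) g@symbols))

unflattenChr <- function(chr, flat) {
  L <- length(chr@genes[[1L]]@symbols)
  for (k in seq_along(chr@genes))
    chr@genes[[k]]@symbols <- flat[((k - 1L) * L + 1L):(k * L)]
  chr
}

opOnePoint <- function(a, b, rate) {
  if (stats::runif(1) >= rate) return(list(a, b))
  fa <- flattenChr(a); fb <- flattenChr(b)
  cut <- sample.int(length(fa) - 1L, 1L)
  idx <- (cut + 1L):length(fa)
  tmp <- fa[idx]; fa[idx] <- fb[idx]; fb[idx] <- tmp
  list(unflattenChr(a, fa), unflattenChr(b, fb))
}

opTwoPoint <- function(a, b, rate) {
  if (stats::runif(1) >= rate) return(list(a, b))
  fa <- flattenChr(a); fb <- flattenChr(b)
  pts <- sort(sample.int(length(fa), 2L))
  idx <- pts[1L]:pts[2L]
  tmp <- fa[idx]; fa[idx] <- fb[idx]; fb[idx] <- tmp
  list(unflattenChr(a, fa), unflattenChr(b, fb))
}

opGeneRecombination <- function(a, b, rate) {
  if (stats::runif(1) >= rate) return(list(a, b))
  k <- sample.int(length(a@genes), 1L)
  tmp <- a@genes[[k]]; a@genes[[k]] <- b@genes[[k]]; b@genes[[k]] <- tmp
  list(a, b)
}

rouletteSelect <- function(fitness, n) {
  w <- fitness
  if (sum(w) <= 0) w <- rep(1, length(fitness))
  sample.int(length(fitness), n, replace = TRUE, prob = w)
}

#' Evolve a symbolic-regression model by gene expression programming
#'
#' Seeded, reproducible evolution: an initial random population is scored by
#' [fitnessR2()], then each generation clones the single best individual
#' (elitism), fills the rest by roulette-wheel selection, and applies
#' mutation, inversion, the three transposition operators and the three
#' recombination operators at the configured rates. Evolution stops when the
#' best fitness reaches `config@fitnessTarget` or after
#' `config@maxGenerations` generations.
#'
#' @param XTrain,yTrain training matrix (terminal-named columns) / response.
#' @param XTest,yTest optional held-out data for the reported test
#'   statistics.
#' @param config a [GEPConfig-class].
#' @param fset optional [FunctionSet-class]; defaults to
#'   [defaultFunctionSet()] over the columns of `XTrain`.
#' @return a [GEPResult-class].
#' @export
evolveGEP <- function(XTrain, yTrain, XTest = NULL, yTest = NULL,
                      config = new("GEPConfig"), fset = NULL) {
  XTrain <- as.matrix(XTrain)
  if (is.null(colnames(XTrain)))
    colnames(XTrain) <- paste0("X", seq_len(ncol(XTrain)) - 1L)
  if (nrow(XTrain) < 5L) stop("need at least 5 training rows")
  validObject(config)
  if (is.null(fset)) fset <- defaultFunctionSet(ncol(XTrain))
  set.seed(config@seed)

  pop <- NULL
  for (attempt in seq_len(20L)) {
    cand <- replicate(config@populationSize, randomChromosome(fset, config),
                      simplify = FALSE)
    valid <- vapply(cand, function(c)
      !anyNA(chromosomePredict(c, XTrain, fset)), logical(1))
    if (any(valid)) { pop <- cand; break }
  }
  if (is.null(pop))
    stop("could not build a valid initial population; try a smaller head length h")

  rates <- config@rates
  best <- NULL; bestFit <- -Inf; bestGen <- 0L
  history <- numeric(0)

  for (gen in seq_len(config@maxGenerations)) {
    fit <- vapply(pop, function(chr) fitnessR2(chr, XTrain, yTrain, fset),
                  numeric(1))
    gi <- which.max(fit)
    if (fit[gi] > bestFit) { bestFit <- fit[gi]; best <- pop[[gi]]; bestGen <- gen }
    history[gen] <- bestFit
    if (bestFit >= config@fitnessTarget) break
    if (gen == config@maxGenerations) break

    parents <- pop[rouletteSelect(fit, config@populationSize - 1L)]
    offspring <- lapply(parents, function(chr) {
      chr <- opMutate(chr, rates["mutation"], fset)
      chr <- opInversion(chr, rates["inversion"])
      chr <- opIsTransposition(chr, rates["isTransposition"])
      chr <- opRisTransposition(chr, rates["risTransposition"], fset)
      opGeneTransposition(chr, rates["geneTransposition"])
    })
    if (length(offspring) >= 2L) {
      for (i in seq(1L, length(offspring) - 1L, by = 2L)) {
        pair <- opOnePoint(offspring[[i]], offspring[[i + 1L]],
                           rates["onePoint"])
        pair <- opTwoPoint(pair[[1L]], pair[[2L]], rates["twoPoint"])
        pair <- opGeneRecombination(pair[[1L]], pair[[2L]],
                                    rates["geneRecombination"])
        offspring[[i]] <- pair[[1L]]
        offspring[[i + 1L]] <- pair[[2L]]
      }
    }
    pop <- c(list(best), offspring)  # elitism: best-so-far always survives
  }

  trainPred <- chromosomePredict(best, XTrain, fset)
  sst <- sum((yTrain - mean(yTrain))^2)
  trainR2 <- if (anyNA(trainPred)) NA_real_
             else 1 - sum((yTrain - trainPred)^2) / sst
  trainMAE <- if (anyNA(trainPred)) NA_real_
              else mean(abs(yTrain - trainPred))
  testR2 <- testMAE <- NA_real_
  if (!is.null(XTest) && !is.null(yTest)) {
    XTest <- as.matrix(XTest)
    if (is.null(colnames(XTest))) colnames(XTest) <- colnames(XTrain)
    testPred <- chromosomePredict(best, XTest, fset)
    if (!anyNA(testPred)) {
      testR2 <- 1 - sum((yTest - testPred)^2) / sum((yTest - mean(yTest))^2)
      testMAE <- mean(abs(yTest - testPred))
    }
  }
  new("GEPResult",
      bestChromosome = best,
      expression = chromosomeToInfix(best, fset),
      trainR2 = trainR2, testR2 = testR2,
      trainMAE = trainMAE, testMAE = testMAE,
      generationFound = bestGen, fitnessHistory = history)
}

setMethod("show", "GEPResult", function(object) {
  cat("GEPResult: best model found at generation", object@generationFound,
      "\n")
  cat(sprintf("  train R2 = %.4f  MAE = %.4f\n",
              object@trainR2, object@trainMAE))
  if (!is.na(object@testR2))
    cat(sprintf("  test  R2 = %.4f  MAE = %.4f\n",
                object@testR2, object@testMAE))
  cat("  expression:", object@expression, "\n")
})

setMethod("show", "Chromosome", function(object) {
  cat("Chromosome with", length(object@genes), "gene(s), linking '",
      object@linking, "'\n", sep = "")
  for (g in object@genes)
    cat("  [h=", g@h, "] ", paste(g@symbols, collapse = " "), "\n", sep = "")
})
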