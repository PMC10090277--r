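## Heuristic linear modelling: OLS with the usual model statistics, a
## descriptor correlation screen, and a beam-width forward selection driven by
## R2 / F / t / cross-validated R2 with a hard pairwise-collinearity cap.

asDescriptorValues <- function(X) {
  if (is(X, "DescriptorMatrix")) X <- descriptorValues(X)
  if (!is.matrix(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)) - 1L)
  X
}

#' Ordinary least squares with QSAR model statistics
#'
#' Fits `y ~ X` by least squares and reports R2, the overall F statistic,
#' per-coefficient t statistics, the residual variance `s2 = RSS/(n-p-1)`,
#' and the leave-one-out cross-validated R2 (computed exactly through the
#' PRESS identity, equivalent to n refits).
#'
#' @param X numeric matrix or [DescriptorMatrix-class] (n x p, n > p + 1).
#' @param y numeric response of length n.
#' @return a [LinearModel-class].
#' @export
fitOLS <- function(X, y) {
  X <- asDescriptorValues(X)
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  n <- nrow(X); p <- ncol(X)
  if (n < p + 1L) stop("need at least columns + 1 rows")
  Z <- cbind("(Intercept)" = 1, X)
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    dep <- colnames(Z)[qrz$pivot[(qrz$rank + 1L):ncol(Z)]]
    stop("rank-deficient design; dependent column: ", dep[1L])
  }
  coef <- qr.coef(qrz, y)
  fitted <- drop(Z %*% coef)
  res <- y - fitted
  rss <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - rss / sst
  dfres <- n - p - 1L
  if (dfres > 0L) {
    s2 <- rss / dfres
    fstat <- (r2 / p) / ((1 - r2) / dfres)
    XtXinv <- chol2inv(qr.R(qrz))[order(qrz$pivot), order(qrz$pivot)]
    se <- sqrt(pmax(s2 * diag(XtXinv), 0))
    tstats <- coef / se
    h <- rowSums(qr.Q(qrz)^2)
    r2cv <- 1 - sum((res / (1 - h))^2) / sst
  } else {
    # saturated fit: the line interpolates; inferential statistics are moot
    s2 <- NA_real_
    fstat <- NA_real_
    tstats <- stats::setNames(rep(NA_real_, p + 1L), names(coef))
    r2cv <- NA_real_
  }
  new("LinearModel",
      intercept = unname(coef[1L]),
      coefficients = coef[-1L],
      tStats = tstats,
      r2 = r2, r2cv = r2cv, s2 = s2, fStat = fstat,
      n = n)
}

#' Predict from a LinearModel
#' @param object a [LinearModel-class]
#' @param newdata matrix or [DescriptorMatrix-class] containing the model's
#'   descriptor columns
#' @param ... unused
#' @return numeric predictions
#' @export
setMethod("predict", "LinearModel", function(object, newdata, ...) {
  X <- asDescriptorValues(newdata)
  miss <- setdiff(names(object@coefficients), colnames(X))
  if (length(miss)) stop("newdata lacks descriptor: ", miss[1L])
  drop(object@intercept +
       X[, names(object@coefficients), drop = FALSE] %*% object@coefficients)
})

#' Pearson correlation matrix of descriptors
#'
#' @param X numeric matrix or [DescriptorMatrix-class]; every column must be
#'   non-constant.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
descriptorCorrelation <- function(X) {
  X <- asDescriptorValues(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column: ", colnames(X)[sds == 0][1L])
  cm <- stats::cor(X)
  diag(cm) <- 1
  cm
}

## ranking used throughout the search: R2 desc, then smallest |t| desc
## (a model whose weakest coefficient is better supported wins ties), then
## lexicographic descriptor names for determinism.
rankModels <- function(models) {
  r2 <- vapply(models, function(m) m@r2, numeric(1))
  minT <- vapply(models, function(m) min(abs(m@tStats[-1L])), numeric(1))
  key <- vapply(models, function(m)
    paste(sort(names(m@coefficients)), collapse = "|"), character(1))
  models[order(-r2, -minT, key)]
}

#' Heuristic forward descriptor selection
#'
#' Beam-width forward selection over descriptor subsets: the best `beam`
#' models of each size are extended by every descriptor whose pairwise
#' Pearson |r| with each already-included descriptor stays below
#' `collinearityMax` (0.8 by default, the conventional multicollinearity
#' cap). Candidate descriptors whose single-descriptor F statistic falls
#' below `fFloor` are pruned before the search. The best model per size is
#' recorded with R2, cross-validated R2 and residual variance; the default
#' chosen size is the last size before the cross-validated-R2 gain drops
#' below `delta`, overridable by inspecting the trace.
#'
#' @param X numeric matrix or [DescriptorMatrix-class], already screened.
#' @param y numeric activities.
#' @param maxSize largest subset size to search (default 7).
#' @param collinearityMax pairwise correlation cap (default 0.8).
#' @param beam number of models kept per size (default 10).
#' @param delta minimum cross-validated-R2 gain to accept a larger model
#'   (default 0.02).
#' @param fFloor single-descriptor F pre-filter (default 1).
#' @return a [SelectionTrace-class].
#' @export
heuristicSearch <- function(X, y, maxSize = 7, collinearityMax = 0.8,
                            beam = 10, delta = 0.02, fFloor = 1) {
  X <- asDescriptorValues(X)
  n <- nrow(X)
  if (n < maxSize + 2L)
    stop("need at least maxSize + 2 compounds")
  maxSize <- min(maxSize, n - 2L)
  cm <- descriptorCorrelation(X)
  vars <- colnames(X)

  singles <- lapply(vars, function(v) fitOLS(X[, v, drop = FALSE], y))
  names(singles) <- vars
  fOK <- vapply(singles, function(m) is.finite(m@fStat) && m@fStat >= fFloor,
                logical(1))
  pool <- vars[fOK]
  if (!length(pool)) stop("no descriptor passes the single-descriptor F filter")

  bestPerSize <- list()
  frontier <- rankModels(singles[pool])
  frontier <- frontier[seq_len(min(beam, length(frontier)))]
  bestPerSize[[1L]] <- frontier[[1L]]

  size <- 1L
  while (size < maxSize) {
    seen <- new.env(parent = emptyenv())
    candidates <- list()
    for (m in frontier) {
      inModel <- names(m@coefficients)
      admissible <- pool[!pool %in% inModel]
      admissible <- admissible[vapply(admissible, function(d)
        all(abs(cm[d, inModel]) < collinearityMax), logical(1))]
      for (d in admissible) {
        cols <- sort(c(inModel, d))
        key <- paste(cols, collapse = "|")
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        fit <- tryCatch(fitOLS(X[, cols, drop = FALSE], y),
                        error = function(e) NULL)
        if (!is.null(fit)) candidates[[length(candidates) + 1L]] <- fit
      }
    }
    if (!length(candidates)) {
      warning("no admissible extension at size ", size + 1L,
              "; selection trace truncated")
      break
    }
    candidates <- rankModels(candidates)
    frontier <- candidates[seq_len(min(beam, length(candidates)))]
    size <- size + 1L
    bestPerSize[[size]] <- frontier[[1L]]
  }

  stats <- data.frame(
    size = seq_along(bestPerSize),
    r2   = vapply(bestPerSize, function(m) m@r2, numeric(1)),
    r2cv = vapply(bestPerSize, function(m) m@r2cv, numeric(1)),
    s2   = vapply(bestPerSize, function(m) m@s2, numeric(1)))

  chosen <- length(bestPerSize)
  if (length(bestPerSize) > 1L) {
    gains <- diff(stats$r2cv)
    stalled <- which(gains < delta)
    if (length(stalled)) chosen <- stalled[1L]
  }
  chosenVars <- names(bestPerSize[[chosen]]@coefficients)
  new("SelectionTrace",
      bestPerSize = bestPerSize, sizeStats = stats,
      chosenSize = as.integer(chosen),
      correlationMatrix = cm[chosenVars, chosenVars, drop = FALSE])
}

#' The model selected by a heuristic search
#' @param trace a [SelectionTrace-class]
#' @param size optional override of the chosen size
#' @return a [LinearModel-class]
#' @export
chosenModel <- function(trace, size = NULL) {
  stopifnot(is(trace, "SelectionTrace"))
  k <- if (is.null(size)) trace@chosenSize else as.integer(size)
  if (k < 1L || k > length(trace@bestPerSize)) stop("no model of size ", k)
  trace@bestPerSize[[k]]
}

setMethod("show", "LinearModel", function(object) {
  cat("LinearModel with", length(object@coefficients), "descriptor(s), n =",
      object@n, "\n")
  cat(sprintf("  R2 = %.4f  R2cv = %.4f  s2 = %.4g  F = %.3f\n",
              object@r2, object@r2cv, object@s2, object@fStat))
  tab <- data.frame(coefficient = c(object@intercept, object@coefficients),
                    t = object@tStats)
  rownames(tab) <- names(object@tStats)
  print(format(tab, digits = 4))
})

setMethod("show", "SelectionTrace", function(object) {
  cat("SelectionTrace over sizes 1..", length(object@bestPerSize),
      "; chosen size ", object@chosenSize, "\n", sep = "")
  print(format(object@sizeStats, digits = 4), row.names = FALSE)
  cat("chosen descriptors:",
      paste(names(chosenModel(object)@coefficients), collapse = ", "), "\n")
})
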