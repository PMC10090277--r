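## NIPALS partial least squares for a single response, with exact
## leave-one-out cross-validation to pick the optimal number of components
## (ONC) by Q2. Columns are centered internally; any scaling (e.g. the
## CoMSIA block scaling) is applied upstream and travels with the X handed
## in, so stored coefficients live on that scale.

plsMatrix <- function(X) {
  if (is(X, "ComsiaFields")) X <- X@values
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  X
}

## core NIPALS on centered data; returns cumulative coefficient vectors
## B[, c] for models with 1..ncomp components
nipalsCoef <- function(Xc, yc, ncomp) {
  p <- ncol(Xc)
  W <- P <- matrix(0, p, ncomp)
  qv <- numeric(ncomp)
  used <- 0L
  for (c in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) break          # nothing left to model (e.g. constant y)
    w <- w / nw
    tt <- drop(Xc %*% w)
    t2 <- sum(tt^2)
    if (t2 < 1e-14) break
    pv <- drop(crossprod(Xc, tt)) / t2
    qc <- sum(yc * tt) / t2
    Xc <- Xc - tcrossprod(tt, pv)
    yc <- yc - qc * tt
    W[, c] <- w; P[, c] <- pv; qv[c] <- qc
    used <- c
  }
  B <- matrix(0, p, ncomp)
  if (used > 0L) {
    for (c in seq_len(used)) {
      Wc <- W[, 1:c, drop = FALSE]
      Pc <- P[, 1:c, drop = FALSE]
      B[, c] <- drop(Wc %*% solve(crossprod(Pc, Wc), qv[1:c]))
    }
    if (used < ncomp) for (c in (used + 1L):ncomp) B[, c] <- B[, used]
  }
  B
}

#' Fit a PLS regression model by NIPALS
#'
#' @param X numeric matrix or [ComsiaFields-class] (n x p), pre-treated as
#'   desired; centered internally.
#' @param y numeric response of length n.
#' @param ncomp number of latent components, `1 <= ncomp <= min(n-1, p)`.
#' @return a [PLSModel-class] with R2, SEE = sqrt(RSS/(n - ncomp - 1)) and
#'   F = (R2/ncomp) / ((1 - R2)/(n - ncomp - 1)).
#' @export
plsFit <- function(X, y, ncomp) {
  X <- plsMatrix(X)
  n <- nrow(X)
  if (n != length(y)) stop("rows of X must match length of y")
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > min(n - 1L, ncol(X)))
    stop("ncomp must lie in 1..min(n-1, p)")
  xm <- colMeans(X); ym <- mean(y)
  B <- nipalsCoef(sweep(X, 2, xm), y - ym, ncomp)
  coefs <- B[, ncomp]
  pred <- drop(sweep(X, 2, xm) %*% coefs) + ym
  rss <- sum((y - pred)^2)
  sst <- sum((y - ym)^2)
  r2 <- if (sst > 0) 1 - rss / sst else NA_real_
  dfres <- n - ncomp - 1L
  see <- if (dfres > 0) sqrt(rss / dfres) else NA_real_
  fstat <- if (dfres > 0 && !is.na(r2) && r2 < 1)
    (r2 / ncomp) / ((1 - r2) / dfres) else Inf
  new("PLSModel", ncomp = ncomp, coefficients = unname(coefs),
      xMeans = unname(xm), yMean = ym, r2 = r2, see = see, fStat = fstat,
      n = n)
}

#' Predict from a PLSModel
#' @param object a [PLSModel-class]
#' @param newdata matrix or [ComsiaFields-class] on the same column layout
#'   and scale the model was fitted on
#' @param ... unused
#' @return numeric predictions
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
  X <- plsMatrix(newdata)
  if (ncol(X) != length(object@coefficients))
    stop("newdata has ", ncol(X), " columns; model expects ",
         length(object@coefficients))
  drop(sweep(X, 2, object@xMeans) %*% object@coefficients) + object@yMean
})

#' Leave-one-out component selection for PLS
#'
#' For each candidate component count c the predictive residual sum of
#' squares PRESS(c) is accumulated from exact leave-one-out refits and
#' Q2(c) = 1 - PRESS(c)/SS is recorded; the optimal number of components
#' (ONC) maximizes Q2 (smallest c on ties, capped at `maxComp`). The
#' returned model is refit on all rows at the ONC and carries the Q2
#' profile.
#'
#' @param X numeric matrix or [ComsiaFields-class] (n >= 4 rows).
#' @param y numeric response.
#' @param maxComp largest component count considered (default 10).
#' @return a [PLSModel-class] with `q2` and `q2Profile` filled.
#' @export
plsLooOnc <- function(X, y, maxComp = 10) {
  X <- plsMatrix(X)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 rows for leave-one-out selection")
  cmax <- min(maxComp, n - 2L, ncol(X))
  press <- numeric(cmax)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    xm <- colMeans(Xi); ym <- mean(yi)
    B <- nipalsCoef(sweep(Xi, 2, xm), yi - ym, cmax)
    predAll <- drop((X[i, ] - xm) %*% B) + ym
    press <- press + (y[i] - predAll)^2
  }
  sst <- sum((y - mean(y))^2)
  q2 <- 1 - press / sst
  onc <- which.max(q2)             # ties resolve to the smaller count
  model <- plsFit(X, y, onc)
  model@q2 <- q2[onc]
  model@q2Profile <- q2
  model
}

#' CoMSIA field PLS analysis
#'
#' The 3D-QSAR modelling step: pretreats the stacked field columns
#' ([comsiaPretreat()]), selects the component count by leave-one-out Q2
#' ([plsLooOnc()]), and derives the contour set and per-field contribution
#' fractions ([contourAndContrib()]).
#'
#' @param fields a raw or pretreated [ComsiaFields-class].
#' @param y numeric activities (one per molecule).
#' @param maxComp largest component count considered (default 10).
#' @param favPct,unfavPct contour percentile levels.
#' @return list with elements `model` (a [PLSModel-class] carrying
#'   `fieldFractions`), `fields` (the pretreated [ComsiaFields-class]) and
#'   `contours` (a [ContourSet-class]).
#' @export
comsiaPLS <- function(fields, y, maxComp = 10, favPct = 80, unfavPct = 20) {
  stopifnot(is(fields, "ComsiaFields"))
  ft <- comsiaPretreat(fields)
  model <- plsLooOnc(ft@values, y, maxComp = maxComp)
  contours <- contourAndContrib(model, ft, favPct = favPct,
                                unfavPct = unfavPct)
  model@fieldFractions <- contours@fieldFractions
  list(model = model, fields = ft, contours = contours)
}

#' Project new molecules onto a pretreated field layout
#'
#' Applies a fitted analysis' pretreatment (column selection and block
#' scales) to raw fields of new molecules, so a [PLSModel-class] can score
#' them.
#'
#' @param newFields raw [ComsiaFields-class] of the new molecules, computed
#'   on the same grid and field types as the template.
#' @param template the pretreated [ComsiaFields-class] from the fit.
#' @return a [ComsiaFields-class] matching the template's column layout.
#' @export
comsiaApplyPretreat <- function(newFields, template) {
  stopifnot(is(newFields, "ComsiaFields"), is(template, "ComsiaFields"),
            template@scaled, !newFields@scaled)
  keyNew <- paste(newFields@fieldLabels, newFields@gridIndex)
  keyTpl <- paste(template@fieldLabels, template@gridIndex)
  idx <- match(keyTpl, keyNew)
  if (anyNA(idx))
    stop("new fields were not computed on the template's grid/fields")
  v <- newFields@values[, idx, drop = FALSE]
  for (f in names(template@blockScales)) {
    sc <- template@blockScales[[f]]
    if (sc > 0) v[, template@fieldLabels == f] <-
        v[, template@fieldLabels == f, drop = FALSE] / sc
  }
  initialize(template, values = v)
}

setMethod("show", "PLSModel", function(object) {
  cat("PLSModel:", object@ncomp, "component(s), n =", object@n, "\n")
  cat(sprintf("  r2 = %.4f  SEE = %.4g  F = %.3f", object@r2, object@see,
              object@fStat))
  if (!is.na(object@q2)) cat(sprintf("  Q2(LOO) = %.4f", object@q2))
  cat("\n")
  if (length(object@fieldFractions)) {
    fr <- object@fieldFractions
    cat("  field contributions:",
        paste(sprintf("%s=%.3f", names(fr), fr), collapse = "  "), "\n")
  }
})
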