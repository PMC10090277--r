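## Seeded generators emulating the statistical structure each modelling
## stage assumes: a descriptor table with a planted sparse linear signal, a
## symbolic-regression target built from the engine's own function set, and
## a pre-aligned pseudo-molecule series with a planted single-field activity
## effect. Every generator is a pure function of its spec, so recovery tests
## need no external data.

#' SyntheticSpec: parameters of the synthetic-data generators
#'
#' @slot seed integer; fixing it makes every generator bit-reproducible.
#' @slot n number of compounds / molecules / rows.
#' @slot p number of descriptor columns (2D generators).
#' @slot plantedSubset integer indices (1-based) of the active descriptors.
#' @slot beta planted coefficients, one per planted descriptor.
#' @slot noiseSD Gaussian noise on the transformed-activity scale, expressed
#'   as a fraction of the planted signal's standard deviation (absolute when
#'   the signal is constant).
#' @slot corBlockSize,corRho optional equicorrelated leading block of
#'   descriptor columns (size 0 disables it).
#' @slot expressionId catalog id of the symbolic target: "f1"
#'   (sin(x0)+x1), "f2" (x0*x1+sin(x2)) or "f3" (x0/x1+Ln(x2), x1,x2 > 0.5).
#' @slot fieldEffect list(site =, field =, effect =) planting an activity
#'   effect on one variable-site property for the 3D generator.
#' @export
setClass("SyntheticSpec",
  representation(seed = "integer", n = "integer", p = "integer",
                 plantedSubset = "integer", beta = "numeric",
                 noiseSD = "numeric", corBlockSize = "integer",
                 corRho = "numeric", expressionId = "character",
                 fieldEffect = "list"),
  prototype(seed = 1L, n = 60L, p = 30L, plantedSubset = c(1L, 4L, 9L),
            beta = c(3, -2, 1.5), noiseSD = 0.1, corBlockSize = 0L,
            corRho = 0, expressionId = "f1",
            fieldEffect = list(site = 8L, field = "E", effect = 2))
)

setValidity("SyntheticSpec", function(object) {
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  if (length(object@plantedSubset) != length(object@beta))
    return("one beta per planted descriptor")
  if (object@corRho < 0 || object@corRho >= 1)
    return("corRho must lie in [0, 1)")
  TRUE
})

#' Convenience constructor for a SyntheticSpec
#' @param ... slot values overriding the prototype defaults
#' @return a [SyntheticSpec-class]
#' @export
syntheticSpec <- function(...) {
  args <- list(...)
  for (k in c("seed", "n", "p", "corBlockSize"))
    if (k %in% names(args)) args[[k]] <- as.integer(args[[k]])
  if ("plantedSubset" %in% names(args))
    args$plantedSubset <- as.integer(args$plantedSubset)
  do.call(new, c(list("SyntheticSpec"), args))
}

noiseFor <- function(signal, noiseSD, n) {
  s <- stats::sd(signal)
  scale <- if (is.finite(s) && s > 0) noiseSD * s else noiseSD
  stats::rnorm(n, sd = scale)
}

#' Generate a descriptor table with a planted sparse linear signal
#'
#' Descriptor columns are standard normal (optionally with an
#' equicorrelated leading block); activities are
#' `5 + sum(beta_k * D_plantedSubset[k]) + noise`, centered near a realistic
#' transformed-activity level so inverse-transformed pseudo-IC50 values stay
#' in a plausible micromolar range.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with `descriptors` (a [DescriptorMatrix-class] with columns
#'   D1..Dp), `activities` (named numeric), and `truth`
#'   (list(subset, beta)).
#' @export
genDescriptorTable <- function(spec) {
  validObject(spec)
  if (any(spec@plantedSubset > spec@p) || any(spec@plantedSubset < 1L))
    stop("planted descriptor index out of range 1..p")
  set.seed(spec@seed)
  n <- spec@n; p <- spec@p
  X <- matrix(stats::rnorm(n * p), n, p)
  if (spec@corBlockSize > 1L && spec@corRho > 0) {
    b <- spec@corBlockSize
    common <- stats::rnorm(n)
    X[, 1:b] <- sqrt(spec@corRho) * common +
      sqrt(1 - spec@corRho) * X[, 1:b]
  }
  ids <- sprintf("M%02d", seq_len(n))
  dimnames(X) <- list(ids, paste0("D", seq_len(p)))
  signal <- drop(X[, spec@plantedSubset, drop = FALSE] %*% spec@beta)
  y <- 5 + signal + noiseFor(signal, spec@noiseSD, n)
  dm <- new("DescriptorMatrix", values = X,
            classes = stats::setNames(rep("imported", p), colnames(X)),
            dropLog = character())
  list(descriptors = dm, activities = stats::setNames(y, ids),
       truth = list(subset = colnames(X)[spec@plantedSubset],
                    beta = spec@beta))
}

SYMBOLIC_CATALOG <- list(
  f1 = list(fn = function(X) sin(X[, 1]) + X[, 2], arity = 2,
            domains = list(c(-3, 3), c(-2, 2))),
  f2 = list(fn = function(X) X[, 1] * X[, 2] + sin(X[, 3]), arity = 3,
            domains = list(c(-2, 2), c(-2, 2), c(-3, 3))),
  ## divisor and log argument sampled well away from their singularities
  f3 = list(fn = function(X) X[, 1] / X[, 2] + log(X[, 3]), arity = 3,
            domains = list(c(-2, 2), c(0.5, 2.5), c(0.5, 2.5)))
)

#' Generate a symbolic-regression dataset from the target catalog
#'
#' The catalog holds targets expressible in the default function set:
#' `f1 = sin(X0) + X1`, `f2 = X0*X1 + sin(X2)`, and
#' `f3 = X0/X1 + Ln(X2)` with `X1, X2` sampled in (0.5, 2.5) so the
#' singularities of division and Ln are excluded by construction. Extra
#' uninformative columns are appended up to `spec@p`.
#'
#' @param spec a [SyntheticSpec-class]; `expressionId` picks the target.
#' @return list with `X` (matrix, columns X0..X(p-1)), `y`, and `truth`
#'   (list(expressionId, fn)).
#' @export
genSymbolicDataset <- function(spec) {
  validObject(spec)
  entry <- SYMBOLIC_CATALOG[[spec@expressionId]]
  if (is.null(entry)) stop("unknown expression_id: ", spec@expressionId)
  set.seed(spec@seed)
  n <- spec@n
  p <- max(spec@p, entry$arity)
  X <- matrix(stats::rnorm(n * p), n, p)
  for (k in seq_len(entry$arity)) {
    d <- entry$domains[[k]]
    X[, k] <- stats::runif(n, d[1], d[2])
  }
  colnames(X) <- paste0("X", seq_len(p) - 1L)
  signal <- entry$fn(X)
  y <- signal + noiseFor(signal, spec@noiseSD, n)
  list(X = X, y = y,
       truth = list(expressionId = spec@expressionId, fn = entry$fn))
}

## fixed rigid scaffold shared by every generated molecule: a near-planar
## seven-atom frame plus the variable substitution site at atom 8
SCAFFOLD_XYZ <- matrix(c(
   0.0,  0.0, 0.0,
   1.4,  0.0, 0.0,
   2.1,  1.2, 0.0,
   1.4,  2.4, 0.2,
   0.0,  2.4, 0.0,
  -0.7,  1.2, -0.2,
  -2.1,  1.2, 0.0,
   3.6,  1.2, 0.4), byrow = TRUE, ncol = 3)

SCAFFOLD_PROPS <- data.frame(
  charge      = c(0.1, -0.1, 0.05, -0.05, 0.1, -0.1, 0.2, 0),
  steric      = c(2, 2, 2, 2, 2, 2, 3, 0),
  hydrophobic = c(0.2, 0.2, -0.3, 0.2, 0.2, -0.3, -0.5, 0),
  donor       = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
  acceptor    = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))

#' Generate a pre-aligned molecule series with a planted field effect
#'
#' All molecules share a fixed rigid pseudo-atom scaffold (identical
#' coordinates, so the series is born aligned, emulating template
#' superposition); one substitution site varies its per-atom properties
#' across molecules, and the activity is a linear function of a single
#' chosen property at that site:
#' `activity = 5 + effect * property(site, field) + noise`.
#'
#' @param spec a [SyntheticSpec-class]; `fieldEffect` names the site (atom
#'   index), field type ("S","E","H","D","A") and effect size.
#' @return list with `molecules` (list of [Molecule3D-class]),
#'   `activities` (named numeric) and `truth` (the fieldEffect plus the
#'   per-molecule site property values).
#' @export
genAlignedMolecules <- function(spec) {
  validObject(spec)
  if (spec@n < 6L) stop("need n >= 6 molecules")
  fe <- spec@fieldEffect
  if (!all(c("site", "field", "effect") %in% names(fe)))
    stop("fieldEffect must name site, field and effect")
  if (!fe$field %in% names(FIELD_PROPERTY))
    stop("planted effect on undefined field: ", fe$field)
  set.seed(spec@seed)
  n <- spec@n
  site <- as.integer(fe$site)
  if (site < 1L || site > nrow(SCAFFOLD_XYZ)) stop("site out of range")
  siteProps <- data.frame(
    charge      = stats::runif(n, -0.5, 0.5),
    steric      = stats::runif(n, 1, 8),
    hydrophobic = stats::runif(n, -1, 1),
    donor       = stats::runif(n) < 0.5,
    acceptor    = stats::runif(n) < 0.5)
  prop <- FIELD_PROPERTY[[fe$field]]
  signal <- fe$effect * as.numeric(siteProps[[prop]])
  y <- 5 + signal + noiseFor(signal, spec@noiseSD, n)
  ids <- sprintf("M%02d", seq_len(n))
  molecules <- lapply(seq_len(n), function(i) {
    at <- data.frame(element = "X",
                     x = SCAFFOLD_XYZ[, 1], y = SCAFFOLD_XYZ[, 2],
                     z = SCAFFOLD_XYZ[, 3], SCAFFOLD_PROPS)
    for (colname in names(siteProps)) at[[colname]][site] <- siteProps[[colname]][i]
    molecule3D(ids[i], at)
  })
  list(molecules = molecules, activities = stats::setNames(y, ids),
       truth = c(fe, list(siteValues = as.numeric(siteProps[[prop]]))))
}
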