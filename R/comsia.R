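## CoMSIA-style 3D-QSAR: rigid Kabsch superposition onto a template,
## Gaussian similarity-index fields evaluated on a rectangular lattice
## extending beyond the aligned set, and (in pls.R) partial least squares on
## the stacked field columns.

VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, X = 1.70)

## coarse atom-level hydrophobicity contributions (Crippen-style in spirit)
HYDROPHOBIC_CONTRIB <- c(H = 0.11, C = 0.14, N = -0.60, O = -0.40, S = 0.40,
                         P = -0.20, F = 0.22, Cl = 0.30, Br = 0.35, I = 0.40,
                         X = 0)

FIELD_PROPERTY <- c(S = "steric", E = "charge", H = "hydrophobic",
                    D = "donor", A = "acceptor")

#' Construct a 3D molecule with per-atom field properties
#'
#' Properties not supplied are filled from element-based defaults: steric
#' weight = (van der Waals radius)^3, charge 0, a coarse atom-level
#' hydrophobicity contribution, and donor/acceptor flags FALSE. Pseudo-atoms
#' (element "X") are accepted so synthetic molecules need no chemistry.
#'
#' @param id molecule identifier.
#' @param atoms data.frame with at least element, x, y, z; optional columns
#'   charge, steric, hydrophobic, donor, acceptor override the defaults.
#' @return a [Molecule3D-class].
#' @export
molecule3D <- function(id, atoms) {
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  el <- as.character(atoms$element)
  known <- ifelse(el %in% names(VDW_RADII), el, "X")
  if (is.null(atoms$steric)) atoms$steric <- VDW_RADII[known]^3
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$hydrophobic)) atoms$hydrophobic <- HYDROPHOBIC_CONTRIB[known]
  if (is.null(atoms$donor)) atoms$donor <- FALSE
  if (is.null(atoms$acceptor)) atoms$acceptor <- FALSE
  atoms$donor <- as.logical(atoms$donor)
  atoms$acceptor <- as.logical(atoms$acceptor)
  rownames(atoms) <- NULL
  new("Molecule3D", id = as.character(id),
      atoms = atoms[, c("element", "x", "y", "z", "charge", "steric",
                        "hydrophobic", "donor", "acceptor")])
}

#' @describeIn Molecule3D atom record table
#' @param x a Molecule3D
#' @export
setMethod("atoms", "Molecule3D", function(x) x@atoms)

#' @describeIn Molecule3D n x 3 coordinate matrix
#' @export
setMethod("coords", "Molecule3D", function(x) {
  as.matrix(x@atoms[, c("x", "y", "z")])
})

setMethod("show", "Molecule3D", function(object) {
  cat("Molecule3D ", object@id, ": ", nrow(object@atoms), " atoms (",
      paste(unique(object@atoms$element), collapse = ","), ")\n", sep = "")
})

#' Read a molecule set from the package's JSON interchange format
#'
#' The format is a JSON array of objects `{id, atoms: [{element, x, y, z,
#' charge, steric, hydrophobic, donor, acceptor}, ...]}` — the same format
#' [genAlignedMolecules()] emits, so synthetic and real inputs are
#' interchangeable.
#'
#' @param path JSON file path.
#' @return list of [Molecule3D-class].
#' @export
readMoleculeSet <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(raw)), function(i)
    molecule3D(raw$id[i], as.data.frame(raw$atoms[[i]])))
}

#' Write a molecule set to the JSON interchange format
#' @param molecules list of [Molecule3D-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeMoleculeSet <- function(molecules, path) {
  payload <- data.frame(id = vapply(molecules, function(m) m@id, character(1)))
  payload$atoms <- lapply(molecules, atoms)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read 3D molecules from an SDF file
#'
#' Coordinates and elements come from the atom block (via ChemmineR);
#' per-atom field properties default as in [molecule3D()], donors/acceptors
#' by the usual rules (N/O bearing a hydrogen donate; N/O accept), and any of
#' the data-block tags `COMSIA_W_S/E/H/D/A` (space-separated per-atom values)
#' override them.
#'
#' @param path SDF file path.
#' @return list of [Molecule3D-class].
#' @export
readMoleculeSDF <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("ChemmineR is required to read SDF files")
  sdfs <- ChemmineR::read.SDFset(path)
  ChemmineR::cid(sdfs) <- ChemmineR::sdfid(sdfs)
  lapply(seq_along(sdfs), function(i) {
    sdf <- sdfs[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    el <- gsub("_.*$", "", rownames(ab))
    n <- nrow(ab)
    hasH <- rep(FALSE, n)
    if (nrow(bb)) {
      for (b in seq_len(nrow(bb))) {
        i1 <- as.integer(bb[b, 1]); i2 <- as.integer(bb[b, 2])
        if (el[i2] == "H") hasH[i1] <- TRUE
        if (el[i1] == "H") hasH[i2] <- TRUE
      }
    } else hasH[] <- TRUE  # no bond table: assume protonated heteroatoms
    at <- data.frame(element = el,
                     x = ab[, 1], y = ab[, 2], z = ab[, 3],
                     donor = el %in% c("N", "O") & hasH,
                     acceptor = el %in% c("N", "O"))
    db <- ChemmineR::datablock(sdf)
    for (f in names(FIELD_PROPERTY)) {
      tag <- paste0("COMSIA_W_", f)
      if (tag %in% names(db)) {
        vals <- as.numeric(strsplit(trimws(db[[tag]]), "\\s+")[[1]])
        if (length(vals) != n)
          stop("tag ", tag, " must give one value per atom")
        prop <- FIELD_PROPERTY[[f]]
        at[[prop]] <- if (prop %in% c("donor", "acceptor")) vals != 0 else vals
      }
    }
    molecule3D(ChemmineR::sdfid(sdfs)[i], at)
  })
}

## ---- alignment -------------------------------------------------------------

#' Rigid superposition of a molecule onto a template (Kabsch)
#'
#' Finds the proper rotation (det = +1) and translation minimizing the RMSD
#' over the given atom pairs, and applies it to every atom of `target`.
#'
#' @param template a [Molecule3D-class].
#' @param target a [Molecule3D-class] to be moved.
#' @param atomPairs two-column integer matrix of (template atom, target atom)
#'   index pairs; defaults to 1:1 pairing when the molecules have equally
#'   many atoms. At least 3 non-collinear pairs are required.
#' @return list with `molecule` (the aligned copy), `rmsd`, `rotation` (3x3)
#'   and `translation` (length 3).
#' @export
kabschAlign <- function(template, target, atomPairs = NULL) {
  P <- coords(template); Q <- coords(target)
  if (is.null(atomPairs)) {
    if (nrow(P) != nrow(Q))
      stop("atomPairs required when atom counts differ")
    atomPairs <- cbind(seq_len(nrow(P)), seq_len(nrow(Q)))
  }
  atomPairs <- as.matrix(atomPairs)
  if (nrow(atomPairs) < 3L) stop("need at least 3 atom pairs")
  p <- P[atomPairs[, 1], , drop = FALSE]
  q <- Q[atomPairs[, 2], , drop = FALSE]
  pc <- colMeans(p); qc <- colMeans(q)
  pm <- sweep(p, 2, pc); qm <- sweep(q, 2, qc)
  if (svd(pm)$d[2] < 1e-8 * max(svd(pm)$d[1], 1))
    stop("atom pairs are collinear; alignment is underdetermined")
  H <- crossprod(qm, pm)          # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- sweep(sweep(Q, 2, qc) %*% t(R), 2, pc, "+")
  out <- target
  out@atoms$x <- moved[, 1]; out@atoms$y <- moved[, 2]; out@atoms$z <- moved[, 3]
  rmsd <- sqrt(mean(rowSums((moved[atomPairs[, 2], , drop = FALSE] -
                             p)^2)))
  list(molecule = out, rmsd = rmsd, rotation = R,
       translation = pc - drop(R %*% qc))
}

## ---- lattice & fields ------------------------------------------------------

#' Build the field lattice around an aligned molecule set
#'
#' A rectangular grid with the given spacing covering the joint bounding box
#' of all atoms, extended by `margin` on every side (defaults: 2 Angstrom
#' spacing, 4 Angstrom margin).
#'
#' @param molecules list of [Molecule3D-class] (or a single molecule).
#' @param spacing lattice spacing in Angstrom, > 0.
#' @param margin extension beyond the bounding box, per side.
#' @return a [GridSpec-class].
#' @export
buildGrid <- function(molecules, spacing = 2, margin = 4) {
  if (is(molecules, "Molecule3D")) molecules <- list(molecules)
  if (!length(molecules)) stop("empty molecule set")
  if (spacing <= 0) stop("spacing must be > 0")
  xyz <- do.call(rbind, lapply(molecules, coords))
  lo <- unname(apply(xyz, 2, min)) - margin
  hi <- unname(apply(xyz, 2, max)) + margin
  counts <- as.integer(ceiling((hi - lo) / spacing - 1e-9)) + 1L
  new("GridSpec", origin = lo, spacing = spacing, counts = counts)
}

#' @describeIn GridSpec lattice point coordinates (x varies fastest)
#' @param x a GridSpec
#' @export
setMethod("gridPoints", "GridSpec", function(x) {
  ax <- lapply(1:3, function(k)
    x@origin[k] + x@spacing * (seq_len(x@counts[k]) - 1L))
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                        KEEP.OUT.ATTRS = FALSE))
})

setMethod("show", "GridSpec", function(object) {
  cat("GridSpec: ", paste(object@counts, collapse = " x "), " points, ",
      "spacing ", object@spacing, " A, origin (",
      paste(sprintf("%.2f", object@origin), collapse = ", "), ")\n", sep = "")
})

#' Similarity-index field of one molecule on a lattice
#'
#' At each lattice point q the field value is the Gaussian-attenuated sum
#' `-(sum over atoms) w_atom * exp(-alpha * r_aq^2)` with unit probe weight
#' (the conventional negative similarity-index sign). The atom property
#' probed is selected by `field`: S steric weight, E partial charge, H
#' hydrophobicity, D/A donor/acceptor flags.
#'
#' @param molecule a [Molecule3D-class].
#' @param grid a [GridSpec-class].
#' @param field one of "S", "E", "H", "D", "A".
#' @param alpha attenuation factor (default 0.3).
#' @return numeric vector of field values, one per lattice point.
#' @export
comsiaField <- function(molecule, grid, field = c("S", "E", "H", "D", "A"),
                        alpha = 0.3) {
  field <- match.arg(field)
  prop <- FIELD_PROPERTY[[field]]
  w <- molecule@atoms[[prop]]
  if (is.null(w) || anyNA(w))
    stop("molecule lacks the per-atom property for field ", field)
  w <- as.numeric(w)
  pts <- gridPoints(grid)
  xyz <- coords(molecule)
  out <- numeric(nrow(pts))
  for (a in seq_len(nrow(xyz))) {
    if (w[a] == 0) next
    d2 <- (pts[, 1] - xyz[a, 1])^2 + (pts[, 2] - xyz[a, 2])^2 +
          (pts[, 3] - xyz[a, 3])^2
    out <- out + w[a] * exp(-alpha * d2)
  }
  -out
}

#' Stacked field columns for a molecule set
#'
#' Evaluates the requested similarity-index fields for every molecule on a
#' common lattice and stacks them into the molecules x columns matrix PLS
#' consumes; columns are grouped into per-field blocks.
#'
#' @param molecules list of [Molecule3D-class].
#' @param grid a [GridSpec-class]; defaults to [buildGrid()] on the set.
#' @param fields subset of c("S","E","H","D","A").
#' @param alpha attenuation factor (default 0.3).
#' @return a [ComsiaFields-class] (raw, not yet pretreated).
#' @export
comsiaFieldMatrix <- function(molecules, grid = NULL,
                              fields = c("S", "E", "H", "D", "A"),
                              alpha = 0.3) {
  if (is.null(grid)) grid <- buildGrid(molecules)
  nPts <- prod(grid@counts)
  blocks <- lapply(fields, function(f) {
    m <- t(vapply(molecules, comsiaField, numeric(nPts), grid = grid,
                  field = f, alpha = alpha))
    colnames(m) <- paste0(f, seq_len(nPts))
    m
  })
  values <- do.call(cbind, blocks)
  rownames(values) <- vapply(molecules, function(m) m@id, character(1))
  new("ComsiaFields", values = values,
      fieldLabels = rep(fields, each = nPts),
      gridIndex = rep(seq_len(nPts), times = length(fields)),
      grid = grid, alpha = alpha, scaled = FALSE)
}

#' Pre-treat field columns for PLS
#'
#' Drops near-constant lattice columns (standard deviation below `sdFloor`,
#' the minimum-sigma analogue) and block-scales each remaining field so its
#' total column variance is 1, so no field dominates purely through its
#' numeric range. Centering is left to the PLS fit.
#'
#' @param fields a raw [ComsiaFields-class].
#' @param sdFloor minimum column standard deviation (default 1e-6).
#' @return a pretreated [ComsiaFields-class] (`scaled = TRUE`).
#' @export
comsiaPretreat <- function(fields, sdFloor = 1e-6) {
  stopifnot(is(fields, "ComsiaFields"))
  if (fields@scaled) return(fields)
  v <- fields@values
  sds <- apply(v, 2, stats::sd)
  keep <- sds >= sdFloor
  if (!any(keep)) stop("no field column varies across molecules")
  v <- v[, keep, drop = FALSE]
  lab <- fields@fieldLabels[keep]
  gi <- fields@gridIndex[keep]
  scales <- numeric(0)
  for (f in unique(lab)) {
    tot <- sum(apply(v[, lab == f, drop = FALSE], 2, stats::var))
    sc <- sqrt(tot)
    if (sc > 0) v[, lab == f] <- v[, lab == f, drop = FALSE] / sc
    scales[f] <- sc
  }
  initialize(fields, values = v, fieldLabels = lab, gridIndex = gi,
             scaled = TRUE, blockScales = scales)
}

setMethod("show", "ComsiaFields", function(object) {
  cat("ComsiaFields: ", nrow(object@values), " molecules x ",
      ncol(object@values), " columns (fields ",
      paste(unique(object@fieldLabels), collapse = ","), "), alpha = ",
      object@alpha, if (object@scaled) ", pretreated" else ", raw",
      "\n", sep = "")
})

#' @describeIn ComsiaFields lattice point coordinates of the underlying grid
#' @param x a ComsiaFields
#' @export
setMethod("gridPoints", "ComsiaFields", function(x) gridPoints(x@grid))

#' Export field columns as a flat CSV (x, y, z, field, value per molecule)
#' @param fields a [ComsiaFields-class]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
writeFieldCSV <- function(fields, path) {
  pts <- gridPoints(fields@grid)
  rows <- lapply(seq_len(nrow(fields@values)), function(i) {
    data.frame(molecule = rownames(fields@values)[i],
               x = pts[fields@gridIndex, 1],
               y = pts[fields@gridIndex, 2],
               z = pts[fields@gridIndex, 3],
               field = fields@fieldLabels,
               value = fields@values[i, ])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

## ---- contours & contributions ---------------------------------------------

#' Contour levels and per-field contribution fractions
#'
#' Scores each retained lattice column as `coefficient x column standard
#' deviation` (the stdev*coeff scale contour maps are drawn on). Field
#' contribution fractions are the per-field sums of |score| normalized to
#' sum 1. Favorable contour levels sit at the `favPct` percentile of the
#' positive scores of each field, unfavorable levels at the `unfavPct`
#' percentile of the negative scores; masks hold the columns at or beyond
#' those levels.
#'
#' @param model a [PLSModel-class] fitted on `fields@values`.
#' @param fields the pretreated [ComsiaFields-class] the model was fit on.
#' @param favPct percentile (of positive scores) for the favorable level.
#' @param unfavPct percentile (of negative scores) for the unfavorable level.
#' @return a [ContourSet-class].
#' @export
contourAndContrib <- function(model, fields, favPct = 80, unfavPct = 20) {
  stopifnot(is(model, "PLSModel"), is(fields, "ComsiaFields"))
  X <- fields@values
  if (length(model@coefficients) != ncol(X))
    stop("model and fields disagree on column count")
  score <- model@coefficients * apply(X, 2, stats::sd)
  lab <- fields@fieldLabels
  fieldsSeen <- unique(lab)
  absSum <- vapply(fieldsSeen, function(f) sum(abs(score[lab == f])),
                   numeric(1))
  if (sum(absSum) == 0) stop("all column scores are zero")
  fractions <- absSum / sum(absSum)
  levels <- data.frame(field = fieldsSeen, favLevel = NA_real_,
                       unfavLevel = NA_real_)
  favMasks <- unfavMasks <- stats::setNames(
    vector("list", length(fieldsSeen)), fieldsSeen)
  for (k in seq_along(fieldsSeen)) {
    f <- fieldsSeen[k]
    s <- score[lab == f]
    idx <- which(lab == f)
    pos <- s[s > 0]; negv <- s[s < 0]
    if (length(pos)) {
      lv <- stats::quantile(pos, favPct / 100, names = FALSE)
      levels$favLevel[k] <- lv
      favMasks[[f]] <- idx[s >= lv]
    } else favMasks[[f]] <- integer(0)
    if (length(negv)) {
      lv <- stats::quantile(negv, unfavPct / 100, names = FALSE)
      levels$unfavLevel[k] <- lv
      unfavMasks[[f]] <- idx[s <= lv]
    } else unfavMasks[[f]] <- integer(0)
  }
  new("ContourSet", levels = levels, favMasks = favMasks,
      unfavMasks = unfavMasks, fieldFractions = fractions)
}

#' @describeIn ContourSet per-field contribution fractions
#' @param x a ContourSet
#' @export
setMethod("fieldFractions", "ContourSet", function(x) x@fieldFractions)

#' @describeIn PLSModel per-field contribution fractions (empty when the
#'   model was fitted without field metadata)
#' @param x a PLSModel
#' @export
setMethod("fieldFractions", "PLSModel", function(x) x@fieldFractions)

setMethod("show", "ContourSet", function(object) {
  cat("ContourSet over fields:",
      paste(object@levels$field, collapse = ", "), "\n")
  fr <- object@fieldFractions
  cat("  contributions:",
      paste(sprintf("%s=%.3f", names(fr), fr), collapse = "  "), "\n")
})
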