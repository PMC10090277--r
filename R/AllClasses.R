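#' @import methods
NULL

#' CompoundSet: a compound-activity table
#'
#' Ordered collection of compounds with IC50 values (micromolar), the
#' transformed activity \code{offset - log10(IC50)}, and a train/test split
#' label. The bundled fixture (see [table1CompoundSet()]) carries the 22
#' dipeptide-alkylated nitrogen-mustard derivatives the pipeline was designed
#' around.
#'
#' @slot records data.frame with columns \code{compound_id}, \code{smiles},
#'   \code{ic50_uM}, \code{activity}, \code{split}.
#' @slot offset numeric scalar used by the activity transform (default 6,
#'   matching micromolar units).
#' @export
setClass("CompoundSet",
  representation(records = "data.frame", offset = "numeric"),
  prototype(records = data.frame(), offset = 6)
)

setValidity("CompoundSet", function(object) {
  rec <- object@records
  need <- c("compound_id", "smiles", "ic50_uM", "activity", "split")
  if (!all(need %in% names(rec)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (nrow(rec) == 0L) return(TRUE)
  if (anyDuplicated(rec$compound_id))
    return(paste0("duplicate compound_id: ",
                  rec$compound_id[duplicated(rec$compound_id)][1L]))
  if (any(!is.finite(rec$ic50_uM)) || any(rec$ic50_uM <= 0))
    return("ic50_uM must be finite and > 0")
  if (any(!is.finite(rec$activity)))
    return("activity must be finite")
  if (!all(rec$split %in% c("train", "test")))
    return("split must be 'train' or 'test'")
  if (length(object@offset) != 1L || !is.finite(object@offset))
    return("offset must be a finite scalar")
  TRUE
})

#' DescriptorMatrix: compounds x named molecular descriptors
#'
#' The X of all 2D models: a numeric matrix whose rows are compounds (in
#' dataset order) and whose columns are named molecular descriptors, each
#' tagged with a descriptor class (constitutional, topological, geometrical,
#' electrostatic, quantum-chemical, or imported).
#'
#' @slot values numeric matrix; rownames are compound ids, colnames descriptor
#'   names.
#' @slot classes named character vector of per-descriptor class tags.
#' @slot dropLog character vector describing columns removed by screening.
#' @export
setClass("DescriptorMatrix",
  representation(values = "matrix", classes = "character",
                 dropLog = "character"),
  prototype(values = matrix(numeric(0), 0, 0), classes = character(),
            dropLog = character())
)

setValidity("DescriptorMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must carry compound ids (rownames) and descriptor names (colnames)")
  if (anyNA(v)) return("values must contain no missing entries after screening")
  if (length(object@classes) != ncol(v) ||
      !identical(names(object@classes), colnames(v)))
    return("classes must be named by descriptor, one per column")
  TRUE
})

#' LinearModel: an ordinary-least-squares QSAR model
#'
#' @slot intercept numeric scalar.
#' @slot coefficients named numeric vector (one per descriptor).
#' @slot tStats named numeric t statistics, intercept first.
#' @slot r2 squared correlation of fit.
#' @slot r2cv leave-one-out cross-validated R2.
#' @slot s2 residual variance RSS/(n - p - 1).
#' @slot fStat overall F statistic.
#' @slot n number of training compounds.
#' @export
setClass("LinearModel",
  representation(intercept = "numeric", coefficients = "numeric",
                 tStats = "numeric", r2 = "numeric", r2cv = "numeric",
                 s2 = "numeric", fStat = "numeric", n = "integer")
)

setValidity("LinearModel", function(object) {
  if (length(object@tStats) != length(object@coefficients) + 1L)
    return("tStats must hold intercept + one value per coefficient")
  if (is.null(names(object@coefficients)))
    return("coefficients must be named by descriptor")
  if (length(object@s2) == 1L && is.finite(object@s2) && object@s2 < 0)
    return("s2 must be non-negative")
  TRUE
})

#' SelectionTrace: the result of the heuristic descriptor search
#'
#' Best model per subset size, the per-size statistics used to choose the
#' model size, and the correlation matrix of the chosen model's descriptors.
#'
#' @slot bestPerSize list of [LinearModel-class], element k = best k-descriptor
#'   model (may stop early if no admissible extension exists).
#' @slot sizeStats data.frame with columns size, r2, r2cv, s2.
#' @slot chosenSize integer, the selected model size.
#' @slot correlationMatrix Pearson correlations of the chosen descriptors.
#' @export
setClass("SelectionTrace",
  representation(bestPerSize = "list", sizeStats = "data.frame",
                 chosenSize = "integer", correlationMatrix = "matrix")
)

setValidity("SelectionTrace", function(object) {
  cm <- object@correlationMatrix
  if (length(cm) > 0) {
    if (nrow(cm) != ncol(cm)) return("correlationMatrix must be square")
    if (max(abs(diag(cm) - 1)) > 1e-12)
      return("correlationMatrix diagonal must be 1")
  }
  if (length(object@chosenSize) == 1L &&
      (object@chosenSize < 1L || object@chosenSize > length(object@bestPerSize)))
    return("chosenSize out of range")
  TRUE
})

## ---- GEP types -------------------------------------------------------------

#' FunctionSet: operators and terminals of the symbolic-regression search
#'
#' @slot ops named list; each element is \code{list(arity =, fn =)}.
#' @slot terminals character vector of terminal symbols (X0, X1, ...).
#' @export
setClass("FunctionSet",
  representation(ops = "list", terminals = "character")
)

setValidity("FunctionSet", function(object) {
  if (length(object@terminals) == 0L) return("terminals must be non-empty")
  if (length(object@ops) == 0L) return("ops must be non-empty")
  ar <- vapply(object@ops, function(o) o$arity, numeric(1))
  if (any(ar < 1)) return("operator arity must be >= 1")
  if (anyDuplicated(c(names(object@ops), object@terminals)))
    return("operator and terminal symbols must be unique")
  TRUE
})

#' Gene: one fixed-length Karva-notation gene
#'
#' A gene of head length h and tail length t = h*(maxArity - 1) + 1; head
#' positions may hold functions or terminals, tail positions terminals only.
#'
#' @slot symbols character vector of length h + t.
#' @slot h integer head length.
#' @export
setClass("Gene", representation(symbols = "character", h = "integer"))

#' Chromosome: a multigenic Karva genome
#'
#' @slot genes list of [Gene-class], all with the same head length.
#' @slot linking linking operator symbol joining the gene sub-expressions.
#' @export
setClass("Chromosome",
  representation(genes = "list", linking = "character"),
  prototype(linking = "+")
)

setValidity("Chromosome", function(object) {
  if (length(object@genes) == 0L) return("at least one gene")
  hs <- vapply(object@genes, function(g) g@h, integer(1))
  if (length(unique(hs)) != 1L) return("all genes must share the head length")
  TRUE
})

#' GEPConfig: evolution parameters
#'
#' Defaults follow canonical gene-expression-programming practice: head
#' length 8, three genes linked by '+', population 50, roulette-wheel
#' selection with a single cloned elite, and the standard operator-rate
#' schedule. All rates act per the usual GEP semantics (mutation per symbol,
#' the structural operators per chromosome).
#'
#' @slot populationSize integer >= 2.
#' @slot maxGenerations integer.
#' @slot h integer head length.
#' @slot nGenes integer number of genes.
#' @slot rates named numeric: mutation, inversion, isTransposition,
#'   risTransposition, geneTransposition, onePoint, twoPoint,
#'   geneRecombination.
#' @slot fitnessTarget stop early when best fitness reaches this value.
#' @slot seed integer seed making the run reproducible.
#' @export
setClass("GEPConfig",
  representation(populationSize = "integer", maxGenerations = "integer",
                 h = "integer", nGenes = "integer", rates = "numeric",
                 fitnessTarget = "numeric", seed = "integer"),
  prototype(populationSize = 50L, maxGenerations = 200L, h = 8L, nGenes = 3L,
            seed = 1L,
            rates = c(mutation = 0.044, inversion = 0.1,
                      isTransposition = 0.1, risTransposition = 0.1,
                      geneTransposition = 0.1, onePoint = 0.3,
                      twoPoint = 0.3, geneRecombination = 0.1),
            fitnessTarget = 0.999999)
)

setValidity("GEPConfig", function(object) {
  if (object@populationSize < 2L) return("populationSize must be >= 2")
  if (object@h < 1L) return("h must be >= 1")
  if (any(object@rates < 0 | object@rates > 1))
    return("operator rates must lie in [0, 1]")
  need <- c("mutation", "inversion", "isTransposition", "risTransposition",
            "geneTransposition", "onePoint", "twoPoint", "geneRecombination")
  if (!all(need %in% names(object@rates)))
    return(paste("rates must name:", paste(need, collapse = ", ")))
  TRUE
})

#' GEPResult: outcome of an evolution run
#'
#' @slot bestChromosome the fittest [Chromosome-class] found.
#' @slot expression printable infix form of the decoded model.
#' @slot trainR2,testR2 coefficient of determination on train / held-out data.
#' @slot trainMAE,testMAE mean absolute error on the transformed-activity
#'   scale.
#' @slot generationFound generation at which the best chromosome appeared.
#' @slot fitnessHistory best-so-far fitness per generation.
#' @export
setClass("GEPResult",
  representation(bestChromosome = "Chromosome", expression = "character",
                 trainR2 = "numeric", testR2 = "numeric",
                 trainMAE = "numeric", testMAE = "numeric",
                 generationFound = "integer", fitnessHistory = "numeric")
)

## ---- 3D types --------------------------------------------------------------

#' Molecule3D: an aligned 3D molecule with per-atom field properties
#'
#' Atom records carry coordinates (Angstrom) plus the five per-atom physico-
#' chemical properties the similarity-index fields probe: partial charge (e),
#' steric weight (conventionally vdW radius cubed), a hydrophobicity
#' contribution, and hydrogen-bond donor/acceptor flags.
#'
#' @slot id molecule identifier.
#' @slot atoms data.frame with columns element, x, y, z, charge, steric,
#'   hydrophobic, donor, acceptor.
#' @export
setClass("Molecule3D",
  representation(id = "character", atoms = "data.frame")
)

setValidity("Molecule3D", function(object) {
  a <- object@atoms
  need <- c("element", "x", "y", "z", "charge", "steric", "hydrophobic",
            "donor", "acceptor")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) < 1L) return("at least one atom")
  if (any(!is.finite(as.matrix(a[, c("x", "y", "z")]))))
    return("coordinates must be finite")
  if (!is.logical(a$donor) || !is.logical(a$acceptor))
    return("donor/acceptor must be logical flags")
  TRUE
})

#' GridSpec: a rectangular lattice around aligned molecules
#'
#' @slot origin numeric xyz of the first lattice point.
#' @slot spacing lattice spacing in Angstrom (default 2).
#' @slot counts integer number of points along x, y, z.
#' @export
setClass("GridSpec",
  representation(origin = "numeric", spacing = "numeric", counts = "integer")
)

setValidity("GridSpec", function(object) {
  if (length(object@origin) != 3L) return("origin must be xyz")
  if (object@spacing <= 0) return("spacing must be > 0")
  if (length(object@counts) != 3L || any(object@counts < 1L))
    return("counts must be three positive integers")
  TRUE
})

#' ComsiaFields: stacked similarity-index field columns
#'
#' One row per molecule; columns are lattice points of each requested field
#' type (S, E, H, D, A), in grid-point-major order within field blocks. After
#' [comsiaPretreat()] the matrix is column-filtered and block-scaled and the
#' pretreatment metadata is recorded.
#'
#' @slot values numeric matrix (molecules x field columns).
#' @slot fieldLabels character per column: "S","E","H","D" or "A".
#' @slot gridIndex integer per column: linear lattice-point index.
#' @slot grid the [GridSpec-class] the fields were evaluated on.
#' @slot alpha Gaussian attenuation factor used.
#' @slot scaled logical: has pretreatment been applied.
#' @slot blockScales named numeric per-field scale divisors (empty if raw).
#' @export
setClass("ComsiaFields",
  representation(values = "matrix", fieldLabels = "character",
                 gridIndex = "integer", grid = "GridSpec", alpha = "numeric",
                 scaled = "logical", blockScales = "numeric"),
  prototype(scaled = FALSE, blockScales = numeric())
)

setValidity("ComsiaFields", function(object) {
  if (ncol(object@values) != length(object@fieldLabels))
    return("one field label per column")
  if (ncol(object@values) != length(object@gridIndex))
    return("one grid index per column")
  if (!all(object@fieldLabels %in% c("S", "E", "H", "D", "A")))
    return("field labels must be S, E, H, D or A")
  TRUE
})

#' PLSModel: a NIPALS partial-least-squares regression model
#'
#' @slot ncomp number of latent components (the ONC when chosen by LOO Q2).
#' @slot coefficients regression coefficients on the scale of the supplied X.
#' @slot xMeans,yMean centering constants.
#' @slot r2 non-cross-validated R2.
#' @slot see standard error of estimate, sqrt(RSS/(n - ncomp - 1)).
#' @slot fStat F statistic with (ncomp, n - ncomp - 1) degrees of freedom.
#' @slot q2 leave-one-out cross-validated R2 (NA unless computed).
#' @slot q2Profile Q2 per candidate component count (empty unless computed).
#' @slot fieldFractions per-field contribution fractions (empty unless field
#'   metadata was available).
#' @slot n number of training rows.
#' @export
setClass("PLSModel",
  representation(ncomp = "integer", coefficients = "numeric",
                 xMeans = "numeric", yMean = "numeric", r2 = "numeric",
                 see = "numeric", fStat = "numeric", q2 = "numeric",
                 q2Profile = "numeric", fieldFractions = "numeric",
                 n = "integer"),
  prototype(q2 = NA_real_, q2Profile = numeric(), fieldFractions = numeric())
)

setValidity("PLSModel", function(object) {
  if (object@ncomp < 1L) return("ncomp must be >= 1")
  if (length(object@coefficients) != length(object@xMeans))
    return("coefficients and xMeans must align")
  if (length(object@fieldFractions) > 0 &&
      abs(sum(object@fieldFractions) - 1) > 1e-9)
    return("fieldFractions must sum to 1")
  TRUE
})

#' ContourSet: favorable/unfavorable lattice regions per field
#'
#' Per-column scores are coefficient x column standard deviation; contour
#' levels are percentiles of the positive and negative scores within each
#' field, and masks hold the lattice columns at or beyond those levels.
#'
#' @slot levels data.frame with columns field, favLevel, unfavLevel.
#' @slot favMasks,unfavMasks named lists of integer column indices per field.
#' @slot fieldFractions named numeric contribution fractions summing to 1.
#' @export
setClass("ContourSet",
  representation(levels = "data.frame", favMasks = "list",
                 unfavMasks = "list", fieldFractions = "numeric")
)

#' ValidationReport: model-quality statistics
#'
#' @slot r2,q2Loo,r2Ext fit, leave-one-out, and external-validation R2.
#' @slot maeTrain,maeTest mean absolute errors.
#' @slot nTrain,nTest split sizes.
#' @slot yTrainMean training-set activity mean used by the external statistic.
#' @slot robust logical: r2Ext strictly above the 0.5 robustness threshold.
#' @export
setClass("ValidationReport",
  representation(r2 = "numeric", q2Loo = "numeric", r2Ext = "numeric",
                 maeTrain = "numeric", maeTest = "numeric", nTrain = "integer",
                 nTest = "integer", yTrainMean = "numeric", robust = "logical")
)
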