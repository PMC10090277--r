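## Descriptor assembly: a handful of descriptors are derivable from the
## molecular graph (atom counts, valencies); everything else — in particular
## the quantum-chemical class — is import-only and arrives as CSV.

STANDARD_VALENCE <- c(H = 1, C = 4, N = 3, O = 2, S = 2, P = 3,
                      F = 1, Cl = 1, Br = 1, I = 1)

#' Build a molecule graph from atoms and bonds
#'
#' The minimal structure the graph descriptors need: element labels plus a
#' bond list with orders (aromatic bonds as 1.5; MOL-file aromatic code 4 is
#' normalized to 1.5). Hydrogens may be explicit or left implicit — implicit
#' counts are resolved from standard valences.
#'
#' @param elements character vector of element symbols.
#' @param bonds data.frame with columns a1, a2, order (empty for a single
#'   atom).
#' @return an object of class `moleculeGraph`.
#' @export
moleculeGraph <- function(elements, bonds = NULL) {
  if (is.null(bonds))
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = numeric())
  stopifnot(all(c("a1", "a2", "order") %in% names(bonds)))
  if (nrow(bonds) && (max(bonds$a1, bonds$a2) > length(elements) ||
                      min(bonds$a1, bonds$a2) < 1))
    stop("bond endpoint out of range")
  bonds$order[bonds$order == 4] <- 1.5
  structure(list(elements = as.character(elements), bonds = bonds),
            class = "moleculeGraph")
}

#' Convert a SMILES string to a molecule graph
#'
#' Parsing is delegated to ChemmineR (OpenBabel backend); only element labels
#' and bond orders are retained.
#'
#' @param smiles a single SMILES string.
#' @return a `moleculeGraph`.
#' @export
smilesToGraph <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("ChemmineR is required to parse SMILES")
  sdf <- ChemmineR::smiles2sdf(smiles)
  sdfToGraph(sdf[[1]])
}

#' Convert one ChemmineR SDF record to a molecule graph
#'
#' @param sdf a `ChemmineR::SDF` object.
#' @return a `moleculeGraph`.
#' @export
sdfToGraph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- gsub("_.*$", "", rownames(ab))
  bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                      order = as.numeric(bb[, 3]))
  moleculeGraph(elements, bonds)
}

#' Graph-derivable molecular descriptors
#'
#' Computes the two descriptors recoverable from connectivity alone:
#' \describe{
#'   \item{NN}{number of nitrogen atoms.}
#'   \item{AVC}{average valency of a carbon atom: mean, over carbons, of the
#'     total bond-order sum including (implicit) hydrogens.}
#' }
#' A molecule without carbon has no AVC; it is reported as `NA`, not zero.
#'
#' @param structure a `moleculeGraph`, SMILES string, or `ChemmineR::SDF`.
#' @return named numeric vector `c(NN =, AVC =)`.
#' @examples
#' computeGraphDescriptors(moleculeGraph(
#'   c("N", "C", "C", "N"),
#'   data.frame(a1 = 1:3, a2 = 2:4, order = 1)))
#' @export
computeGraphDescriptors <- function(structure) {
  g <- if (inherits(structure, "moleculeGraph")) structure
       else if (is.character(structure) && length(structure) == 1L)
         smilesToGraph(structure)
       else if (inherits(structure, "SDF")) sdfToGraph(structure)
       else stop("structure must be a moleculeGraph, SMILES string or SDF")
  elements <- g$elements
  nn <- sum(elements == "N")
  carbons <- which(elements == "C")
  if (!length(carbons)) return(c(NN = nn, AVC = NA_real_))
  explicit <- vapply(carbons, function(i) {
    sum(g$bonds$order[g$bonds$a1 == i | g$bonds$a2 == i])
  }, numeric(1))
  # heavy-atom files omit H; top valency up to the standard 4 of carbon
  implicitH <- pmax(0, STANDARD_VALENCE[["C"]] - explicit)
  c(NN = nn, AVC = mean(explicit + implicitH))
}

#' Assemble and screen the descriptor matrix
#'
#' Merges externally computed descriptor tables (CSV: first column
#' `compound_id`, remaining columns named descriptors) with graph-derived
#' per-compound value maps, reorders rows to dataset order, then screens:
#' columns with any missing value are dropped, as are columns whose variance
#' falls below `varianceFloor`. Screening is idempotent and every removal is
#' recorded in the drop log.
#'
#' @param dataset a [CompoundSet-class].
#' @param imported character vector of CSV paths (optional).
#' @param computed named list keyed by compound id, each element a named
#'   numeric vector of descriptor values (optional).
#' @param varianceFloor minimum retained column variance (default 1e-8).
#' @param classes named character vector tagging descriptors with a class
#'   (constitutional/topological/geometrical/electrostatic/quantum-chemical);
#'   untagged imports default to "imported". A sidecar JSON file mapping
#'   names to tags may be given instead of a vector.
#' @return a [DescriptorMatrix-class] with rows in dataset order.
#' @export
assembleDescriptors <- function(dataset, imported = character(),
                                computed = NULL, varianceFloor = 1e-8,
                                classes = NULL) {
  stopifnot(is(dataset, "CompoundSet"))
  ids <- compoundIds(dataset)
  pieces <- list()
  for (path in imported) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    rn <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- rn
    pieces[[length(pieces) + 1L]] <- m
  }
  if (!is.null(computed)) {
    allNames <- unique(unlist(lapply(computed, names)))
    m <- matrix(NA_real_, length(computed), length(allNames),
                dimnames = list(names(computed), allNames))
    for (id in names(computed)) m[id, names(computed[[id]])] <- computed[[id]]
    pieces[[length(pieces) + 1L]] <- m
  }
  if (!length(pieces)) stop("no descriptor sources given")
  covered <- unique(unlist(lapply(pieces, rownames)))
  missing <- setdiff(ids, covered)
  if (length(missing))
    stop("compound absent from all descriptor sources: ", missing[1L])
  blocks <- lapply(pieces, function(m) {
    out <- matrix(NA_real_, length(ids), ncol(m),
                  dimnames = list(ids, colnames(m)))
    hit <- intersect(ids, rownames(m))
    out[hit, ] <- m[hit, , drop = FALSE]
    out
  })
  values <- do.call(cbind, blocks)
  if (anyDuplicated(colnames(values)))
    stop("duplicate descriptor name across sources: ",
         colnames(values)[duplicated(colnames(values))][1L])

  dropLog <- character()
  hasNA <- apply(values, 2, anyNA)
  if (any(hasNA)) {
    dropLog <- c(dropLog, paste0("missing-values: ",
                                 colnames(values)[hasNA]))
    values <- values[, !hasNA, drop = FALSE]
  }
  v <- apply(values, 2, stats::var)
  low <- v < varianceFloor
  if (any(low)) {
    dropLog <- c(dropLog, paste0("low-variance: ", colnames(values)[low]))
    values <- values[, !low, drop = FALSE]
  }

  if (is.character(classes) && length(classes) == 1L && file.exists(classes))
    classes <- unlist(jsonlite::read_json(classes, simplifyVector = TRUE))
  tags <- stats::setNames(rep("imported", ncol(values)), colnames(values))
  if (!is.null(classes)) {
    hit <- intersect(names(classes), names(tags))
    tags[hit] <- classes[hit]
  }
  new("DescriptorMatrix", values = values, classes = tags, dropLog = dropLog)
}

## ---- accessors & show ------------------------------------------------------

#' @describeIn DescriptorMatrix the numeric matrix
#' @param x a DescriptorMatrix
#' @export
setMethod("descriptorValues", "DescriptorMatrix", function(x) x@values)

#' @describeIn DescriptorMatrix descriptor names
#' @export
setMethod("descriptorNames", "DescriptorMatrix", function(x) colnames(x@values))

#' @describeIn DescriptorMatrix per-descriptor class tags
#' @export
setMethod("descriptorClasses", "DescriptorMatrix", function(x) x@classes)

#' @describeIn DescriptorMatrix compound ids (row order)
#' @export
setMethod("compoundIds", "DescriptorMatrix", function(x) rownames(x@values))

#' Dimensions of a DescriptorMatrix
#' @param x a DescriptorMatrix
#' @export
setMethod("dim", "DescriptorMatrix", function(x) dim(x@values))

#' Subset descriptors/compounds
#' @param x a DescriptorMatrix
#' @param i row (compound) index
#' @param j column (descriptor) index
#' @param ... unused
#' @param drop unused
#' @export
setMethod("[", "DescriptorMatrix", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  new("DescriptorMatrix", values = v, classes = x@classes[colnames(v)],
      dropLog = x@dropLog)
})

setMethod("show", "DescriptorMatrix", function(object) {
  cat("DescriptorMatrix:", nrow(object@values), "compounds x",
      ncol(object@values), "descriptors\n")
  tb <- table(object@classes)
  cat("  classes:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  if (length(object@dropLog))
    cat("  screened out:", length(object@dropLog), "column(s)\n")
})
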