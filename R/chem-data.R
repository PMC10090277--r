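#' Transform an IC50 (micromolar) to the modelling activity scale
#'
#' Activities are modelled on the negative-log scale, `offset - log10(IC50)`,
#' with the default offset of 6 playing the role of the micromolar-to-molar
#' conversion: a 1 uM inhibitor maps to 6.0 and more potent compounds (lower
#' IC50) map to larger activities. The transform is strictly decreasing in
#' IC50.
#'
#' @param ic50_uM positive numeric vector of IC50 values in micromolar.
#' @param offset numeric scalar added after the negative log (default 6).
#' @return numeric vector `offset - log10(ic50_uM)`.
#' @examples
#' pic50Transform(1)    # 6
#' pic50Transform(1.7)  # 5.7696...
#' @export
pic50Transform <- function(ic50_uM, offset = 6) {
  if (!is.numeric(ic50_uM) || any(!is.finite(ic50_uM)) || any(ic50_uM <= 0))
    stop("ic50_uM must be finite and strictly positive")
  offset - log10(ic50_uM)
}

#' Invert the activity transform back to an IC50 in micromolar
#'
#' @param activity numeric vector on the transformed scale.
#' @param offset the offset used by [pic50Transform()].
#' @return positive numeric IC50 values in micromolar.
#' @export
pic50Invert <- function(activity, offset = 6) 10^(offset - activity)

#' Read a compound-activity CSV into a CompoundSet
#'
#' Expected dialect: UTF-8 with a header row and columns `id`,
#' `smiles` (optional), `ic50_uM`, `split` (optional; values train/test —
#' when absent every compound is labelled train). Row order is preserved.
#'
#' @param path CSV file path.
#' @param offset activity-transform offset passed to [pic50Transform()].
#' @param schema named character vector remapping nonstandard column names,
#'   e.g. `c(id = "NO", ic50_uM = "IC50")`.
#' @return a [CompoundSet-class].
#' @export
readCompoundTable <- function(path, offset = 6, schema = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    for (std in names(schema)) {
      src <- schema[[std]]
      if (!src %in% names(raw))
        stop("schema column not found in CSV: ", src)
      names(raw)[names(raw) == src] <- std
    }
  }
  if (!all(c("id", "ic50_uM") %in% names(raw)))
    stop("CSV must have 'id' and 'ic50_uM' columns")
  ids <- as.character(raw$id)
  if (anyDuplicated(ids))
    stop("duplicate compound id: ", ids[duplicated(ids)][1L])
  ic50 <- suppressWarnings(as.numeric(raw$ic50_uM))
  bad <- which(!is.finite(ic50) | ic50 <= 0)
  if (length(bad))
    stop("non-positive or non-numeric ic50_uM in row ", bad[1L],
         " (id ", ids[bad[1L]], ")")
  split <- if ("split" %in% names(raw)) as.character(raw$split)
           else rep("train", nrow(raw))
  if (!all(split %in% c("train", "test")))
    stop("split column must contain only 'train'/'test'")
  smiles <- if ("smiles" %in% names(raw)) as.character(raw$smiles)
            else rep(NA_character_, nrow(raw))
  new("CompoundSet",
      records = data.frame(compound_id = ids, smiles = smiles,
                           ic50_uM = ic50,
                           activity = pic50Transform(ic50, offset),
                           split = split, stringsAsFactors = FALSE),
      offset = offset)
}

#' Write a CompoundSet back to the CSV dialect [readCompoundTable()] reads
#'
#' @param x a [CompoundSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCompoundTable <- function(x, path) {
  stopifnot(is(x, "CompoundSet"))
  out <- x@records[, c("compound_id", "smiles", "ic50_uM", "split")]
  names(out)[1] <- "id"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' The bundled 22-compound nitrogen-mustard activity table
#'
#' Loads the packaged fixture of 22 dipeptide-alkylated nitrogen-mustard
#' derivatives (ids I1..I22) with their anti-osteosarcoma IC50 values in
#' micromolar and the four-compound external test split used by the 2D
#' models (I3, I4, I14, I20).
#'
#' @param offset activity-transform offset (default 6).
#' @return a [CompoundSet-class] with 22 records.
#' @export
table1CompoundSet <- function(offset = 6) {
  readCompoundTable(system.file("extdata", "nitrogen_mustard_ic50.csv",
                                package = "mustardQSAR", mustWork = TRUE),
                    offset = offset)
}

#' Draw a train/test split for a CompoundSet
#'
#' Replaces any existing labels with a seeded random split, so that the
#' partition is reproducible rather than dependent on system state.
#'
#' @param x a [CompoundSet-class].
#' @param nTest number of test compounds.
#' @param seed integer seed.
#' @return `x` with updated split labels.
#' @export
assignSplit <- function(x, nTest, seed) {
  stopifnot(is(x, "CompoundSet"), nTest >= 1, nTest < nrow(x@records))
  set.seed(seed)
  idx <- sample.int(nrow(x@records), nTest)
  x@records$split <- "train"
  x@records$split[idx] <- "test"
  validObject(x)
  x
}

## ---- accessors & show ------------------------------------------------------

#' @describeIn CompoundSet compound ids in table order
#' @param x a CompoundSet
#' @export
setMethod("compoundIds", "CompoundSet", function(x) x@records$compound_id)

#' @describeIn CompoundSet named transformed activities
#' @export
setMethod("activities", "CompoundSet", function(x) {
  stats::setNames(x@records$activity, x@records$compound_id)
})

#' @describeIn CompoundSet named IC50 values (micromolar)
#' @export
setMethod("ic50Values", "CompoundSet", function(x) {
  stats::setNames(x@records$ic50_uM, x@records$compound_id)
})

#' @describeIn CompoundSet named train/test labels
#' @export
setMethod("splitLabels", "CompoundSet", function(x) {
  stats::setNames(x@records$split, x@records$compound_id)
})

#' Subset a CompoundSet by index, id or logical mask
#' @param x a CompoundSet
#' @param i numeric/logical/character index over compounds
#' @param j unused
#' @param ... unused
#' @param drop unused
#' @export
setMethod("[", "CompoundSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@records$compound_id)
  if (anyNA(i)) stop("unknown compound id")
  initialize(x, records = x@records[i, , drop = FALSE])
})

#' Number of compounds
#' @param x a CompoundSet
#' @export
setMethod("length", "CompoundSet", function(x) nrow(x@records))

setMethod("show", "CompoundSet", function(object) {
  rec <- object@records
  cat("CompoundSet with", nrow(rec), "compounds",
      sprintf("(%d train / %d test)\n",
              sum(rec$split == "train"), sum(rec$split == "test")))
  if (nrow(rec)) {
    cat("  activity = ", object@offset, " - log10(IC50/uM), range [",
        sprintf("%.3f", min(rec$activity)), ", ",
        sprintf("%.3f", max(rec$activity)), "]\n", sep = "")
    cat("  ids:", paste(utils::head(rec$compound_id, 6), collapse = ", "),
        if (nrow(rec) > 6) "..." else "", "\n")
  }
})
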