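#' Compound identifiers
#' @param x a CompoundSet, DescriptorMatrix or other compound container
#' @return character vector of compound ids, in storage order
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' Transformed activities
#' @param x a CompoundSet
#' @return named numeric vector of transformed activities
#' @export
setGeneric("activities", function(x) standardGeneric("activities"))

#' IC50 values (micromolar)
#' @param x a CompoundSet
#' @return named numeric vector of IC50 values
#' @export
setGeneric("ic50Values", function(x) standardGeneric("ic50Values"))

#' Train/test split labels
#' @param x a CompoundSet
#' @return named character vector with values "train"/"test"
#' @export
setGeneric("splitLabels", function(x) standardGeneric("splitLabels"))

#' Descriptor value matrix
#' @param x a DescriptorMatrix
#' @return numeric matrix, compounds x descriptors
#' @export
setGeneric("descriptorValues", function(x) standardGeneric("descriptorValues"))

#' Descriptor names
#' @param x a DescriptorMatrix
#' @return character vector of descriptor names
#' @export
setGeneric("descriptorNames", function(x) standardGeneric("descriptorNames"))

#' Descriptor class tags
#' @param x a DescriptorMatrix
#' @return named character vector of class tags
#' @export
setGeneric("descriptorClasses", function(x) standardGeneric("descriptorClasses"))

#' Atom table of a 3D molecule
#' @param x a Molecule3D
#' @return data.frame of atom records
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Atom coordinates
#' @param x a Molecule3D
#' @return numeric matrix n_atoms x 3
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Lattice point coordinates of a grid
#' @param x a GridSpec or ComsiaFields
#' @return numeric matrix n_points x 3, x-fastest ordering
#' @export
setGeneric("gridPoints", function(x) standardGeneric("gridPoints"))

#' Per-field contribution fractions
#' @param x a PLSModel or ContourSet
#' @return named numeric vector summing to 1 (empty when unavailable)
#' @export
setGeneric("fieldFractions", function(x) standardGeneric("fieldFractions"))
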