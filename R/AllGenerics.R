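#' @include AllClasses.R
NULL

#' Resolve a generic position to a wild-type residue number
#'
#' @param ann a [DomainAnnotation-class].
#' @param gn a [GenericNumber-class] (or a label string, parsed first).
#' @return integer residue number(s), one per position in `gn`.
#' @export
setGeneric("resolvePosition", function(ann, gn)
  standardGeneric("resolvePosition"))

#' Assign a generic position to a wild-type residue number
#'
#' The left inverse of [resolvePosition()]: loop and terminal residues,
#' which carry no generic number, give `NULL`.
#'
#' @param ann a [DomainAnnotation-class].
#' @param residue integer residue number within the domain range.
#' @return A [GenericNumber-class] of length 1, or `NULL` for residues
#'   without a generic number.
#' @export
setGeneric("assignPosition", function(ann, residue)
  standardGeneric("assignPosition"))

#' Protein identifier of an annotation
#'
#' @param x a [DomainAnnotation-class].
#' @return character.
#' @rdname proteinId
#' @export
setGeneric("proteinId", function(x) standardGeneric("proteinId"))

#' Generic-position to residue-number map
#'
#' @param x a [DomainAnnotation-class].
#' @return data.frame(segment, index, residue).
#' @rdname positionMap
#' @export
setGeneric("positionMap", function(x) standardGeneric("positionMap"))

#' Atom table of a structure
#'
#' @param x a [StructureModel-class] or [DomainStructure-class].
#' @return data.frame of atoms.
#' @rdname atoms
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Domain annotation attached to a structure
#'
#' @param x a [DomainStructure-class].
#' @return a [DomainAnnotation-class].
#' @rdname annotation-accessor
#' @export
setGeneric("annotation", function(x) standardGeneric("annotation"))

#' Mutations recorded during renumbering
#'
#' @param x a [DomainStructure-class].
#' @return data.frame(wt, pos, observed).
#' @rdname mutations
#' @export
setGeneric("mutations", function(x) standardGeneric("mutations"))
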