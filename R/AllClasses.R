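#' @import methods
NULL

## Segment vocabulary. aB' (the STAT-family helix, "Evolutionary Active
## Region") is stored with an ASCII apostrophe; aBp and the Unicode prime
## are accepted on input.
.SEGMENTS <- c("bA", "aA", "bB", "bBbC", "bC", "bD", "bE", "bF", "aB'", "aB")
.HELICES <- c("aA", "aB'", "aB")
.STRANDS <- c("bA", "bB", "bC", "bD", "bE", "bF")
.TURNS <- "bBbC"
.ANCHOR_INDEX <- 50L

#' GenericNumber: a segment label plus an integer index
#'
#' The addressing unit of the generic numbering scheme. A position such as
#' `bBx50` names the most conserved position (`x50`) of the bB strand;
#' neighbours within the same segment are numbered sequentially (`bBx49`,
#' `bBx51`, ...). The object is vectorised: `segment` and `index` are
#' parallel vectors.
#'
#' @slot segment character vector of segment labels (one of bA, aA, bB,
#'   bBbC, bC, bD, bE, bF, aB', aB).
#' @slot index integer vector of positive position indices (typically
#'   40--60).
#' @export
setClass("GenericNumber",
  representation(segment = "character", index = "integer"))

setValidity("GenericNumber", function(object) {
  if (length(object@segment) != length(object@index))
    return("segment and index must have equal length")
  bad <- setdiff(object@segment, .SEGMENTS)
  if (length(bad))
    return(paste0("unknown segment(s): ", paste(bad, collapse = ", ")))
  if (length(object@index) && any(is.na(object@index) | object@index < 1L))
    return("index must be a positive integer")
  TRUE
})

#' Construct a GenericNumber
#'
#' @param segment character vector of segment labels. The aliases `aBp`
#'   and the Unicode-prime spelling are normalised to `aB'`.
#' @param index integer vector of positive indices, recycled to the
#'   length of `segment`.
#' @return A [GenericNumber-class] object.
#' @examples
#' GenericNumber("bB", 50)
#' GenericNumber(c("bD", "aA"), c(50, 43))
#' @export
GenericNumber <- function(segment, index) {
  segment <- .normalizeSegment(as.character(segment))
  index <- suppressWarnings(as.integer(index))
  if (length(index) == 1L && length(segment) > 1L)
    index <- rep(index, length(segment))
  if (length(segment) == 1L && length(index) > 1L)
    segment <- rep(segment, length(index))
  new("GenericNumber", segment = segment, index = index)
}

.normalizeSegment <- function(segment) {
  segment[segment == "aBp"] <- "aB'"
  segment[segment == "aB′"] <- "aB'"
  segment
}

#' SchemeDefinition: segment layouts and scheme constants
#'
#' Holds the ordered segment layouts of the SH2 fold. The common layout is
#' the canonical alpha-beta-beta-beta-alpha arrangement (bA, aA, bB, bBbC,
#' bC, bD, bE, bF, aB); the STAT layout lacks the bE and bF strands and
#' instead carries the aB' helix between bD and aB. Also stores the eight
#' Sheinerman phosphotyrosine-pocket positions, the FLVR-motif exception
#' proteins (whose bBx50 arginine is replaced by an aromatic residue), and
#' per-segment generic-index spans.
#'
#' @slot segmentsCommon data.frame with columns `name`, `kind`
#'   (helix/strand/turn) and `rank` for the common layout.
#' @slot segmentsStat same, for the STAT layout.
#' @slot sheinerman [GenericNumber-class] of length 8.
#' @slot flvrExceptions character vector of protein identifiers.
#' @slot anchorIndex the anchor index (50).
#' @slot version scheme resource version string.
#' @export
setClass("SchemeDefinition",
  representation(segmentsCommon = "data.frame", segmentsStat = "data.frame",
    sheinerman = "GenericNumber", flvrExceptions = "character",
    anchorIndex = "integer", version = "character"))

setValidity("SchemeDefinition", function(object) {
  segs <- rbind(object@segmentsCommon, object@segmentsStat)
  helices <- unique(segs$name[segs$kind == "helix"])
  strands <- unique(segs$name[segs$kind == "strand"])
  if (length(helices) != 3L)
    return("scheme must define exactly 3 distinct helix names")
  if (length(strands) != 6L)
    return("scheme must define exactly 6 distinct strand names")
  if (any(substr(helices, 1, 1) != "a"))
    return("helix names must begin with 'a'")
  if (any(substr(strands, 1, 1) != "b"))
    return("strand names must begin with 'b'")
  if (length(object@sheinerman) != 8L)
    return("sheinerman set must contain exactly 8 positions")
  stat <- object@segmentsStat$name
  if (any(c("bE", "bF") %in% stat) || !"aB'" %in% stat)
    return("STAT layout must lack bE/bF and contain aB'")
  if (any("aB'" %in% object@segmentsCommon$name))
    return("common layout must lack aB'")
  TRUE
})

#' DomainAnnotation: generic positions mapped to wild-type residues
#'
#' The per-protein (per-domain) realisation of the scheme: a mapping from
#' generic positions to 1-based wild-type residue numbers, together with
#' the set of segments for which within-segment arithmetic (residue =
#' anchor + index offset) is declared valid.
#'
#' @slot proteinId protein identifier (e.g. "STAT5B").
#' @slot domainSlot "N" or "C" (N- or C-terminal SH2 domain).
#' @slot layout "common" or "STAT".
#' @slot positionMap data.frame with columns `segment`, `index`,
#'   `residue`: the explicit generic-position to residue-number map.
#' @slot contiguous character vector of segment labels for which the map
#'   is a contiguous arithmetic span.
#' @slot sequence optional one-letter amino-acid string (NA if absent).
#' @slot seqOffset residue number of the first sequence character.
#' @export
setClass("DomainAnnotation",
  representation(proteinId = "character", domainSlot = "character",
    layout = "character", positionMap = "data.frame",
    contiguous = "character", sequence = "character",
    seqOffset = "integer"))

#' Construct a DomainAnnotation
#'
#' Contiguous segments may be given compactly as `spans` (one anchor plus
#' an inclusive generic-index range); they are expanded to the full
#' position map by sequential within-segment numbering.
#'
#' @param proteinId,domainSlot,layout see [DomainAnnotation-class].
#' @param anchors data.frame(segment, index, residue): one known
#'   generic-position/residue pair per segment to be expanded.
#' @param spans data.frame(segment, indexMin, indexMax): inclusive
#'   generic-index spans for the anchored segments.
#' @param positionMap optional explicit data.frame(segment, index,
#'   residue) rows appended verbatim (marked non-contiguous unless listed
#'   in `contiguous`).
#' @param contiguous segments with valid arithmetic resolution; defaults
#'   to the anchored/spanned segments.
#' @param sequence optional one-letter sequence; `seqOffset` is the
#'   residue number of its first character.
#' @param seqOffset integer, default 1.
#' @param check validate monotonicity/uniqueness invariants (default
#'   TRUE). Set FALSE only to build deliberately inconsistent annotations
#'   for inspection by [validateAnnotation()].
#' @return A [DomainAnnotation-class] object.
#' @examples
#' stat5b <- DomainAnnotation("STAT5B", layout = "STAT",
#'   anchors = data.frame(segment = "bB", index = 50, residue = 618),
#'   spans = data.frame(segment = "bB", indexMin = 46, indexMax = 52))
#' resolvePosition(stat5b, GenericNumber("bB", 52))
#' @export
DomainAnnotation <- function(proteinId, domainSlot = "N",
    layout = c("common", "STAT"), anchors = NULL, spans = NULL,
    positionMap = NULL, contiguous = NULL, sequence = NA_character_,
    seqOffset = 1L, check = TRUE) {
  layout <- match.arg(layout)
  pm <- data.frame(segment = character(), index = integer(),
    residue = integer())
  if (!is.null(anchors)) {
    if (is.null(spans))
      stop("anchors require spans giving each segment's index range")
    for (k in seq_len(nrow(anchors))) {
      seg <- as.character(anchors$segment[k])
      sp <- spans[spans$segment == seg, , drop = FALSE]
      if (nrow(sp) != 1L)
        stop("no unique span for segment ", seg)
      idx <- seq.int(sp$indexMin, sp$indexMax)
      if (!(anchors$index[k] %in% idx))
        stop("anchor index ", anchors$index[k], " outside span of ", seg)
      pm <- rbind(pm, data.frame(segment = seg, index = as.integer(idx),
        residue = as.integer(anchors$residue[k] + idx - anchors$index[k])))
    }
    if (is.null(contiguous))
      contiguous <- as.character(unique(anchors$segment))
  }
  if (!is.null(positionMap)) {
    pm <- rbind(pm, data.frame(segment = as.character(positionMap$segment),
      index = as.integer(positionMap$index),
      residue = as.integer(positionMap$residue)))
  }
  if (is.null(contiguous)) contiguous <- character()
  pm <- pm[order(match(pm$segment, .SEGMENTS), pm$index), , drop = FALSE]
  rownames(pm) <- NULL
  ann <- new("DomainAnnotation", proteinId = as.character(proteinId),
    domainSlot = as.character(domainSlot), layout = layout,
    positionMap = pm, contiguous = as.character(contiguous),
    sequence = as.character(sequence), seqOffset = as.integer(seqOffset))
  if (check) {
    bad <- .annotationErrors(ann)
    if (length(bad)) stop(paste(bad, collapse = "; "))
  }
  ann
}

## Structural invariants of an annotation, returned as messages (used by
## both the constructor and validateAnnotation).
.annotationErrors <- function(ann) {
  pm <- ann@positionMap
  msgs <- character()
  for (seg in unique(pm$segment)) {
    sub <- pm[pm$segment == seg, , drop = FALSE]
    sub <- sub[order(sub$index), , drop = FALSE]
    if (any(duplicated(sub$index))) {
      msgs <- c(msgs, paste0("segment ", seg, ": duplicated generic index"))
      next
    }
    if (nrow(sub) > 1L && any(diff(sub$residue) <= 0L))
      msgs <- c(msgs, paste0("segment ", seg,
        ": residue numbers not strictly increasing with index"))
    if (seg %in% ann@contiguous &&
        !all(sub$residue - sub$index == sub$residue[1L] - sub$index[1L]))
      msgs <- c(msgs, paste0("segment ", seg,
        ": declared contiguous but map is not arithmetic"))
  }
  if (any(duplicated(pm$residue)))
    msgs <- c(msgs, "a residue number appears under two generic positions")
  msgs
}

#' StructureModel: parsed atomic coordinates
#'
#' @slot atoms data.frame with columns `type`, `eleno`, `elety`, `alt`,
#'   `resid`, `chain`, `resno`, `insert`, `x`, `y`, `z`, `o`, `b`.
#' @slot metadata list (entry id, experimental method, resolution,
#'   recorded transforms, ...).
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", metadata = "list"))

setValidity("StructureModel", function(object) {
  need <- c("type", "eleno", "elety", "alt", "resid", "chain", "resno",
    "insert", "x", "y", "z", "o", "b")
  miss <- setdiff(need, names(object@atoms))
  if (length(miss))
    return(paste0("atoms lacks column(s): ", paste(miss, collapse = ", ")))
  xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
  if (length(xyz) && !all(is.finite(xyz)))
    return("coordinates must be finite")
  TRUE
})

#' DomainStructure: a renumbered, trimmed single-SH2-domain structure
#'
#' @slot parent entry id + chain of origin (e.g. "6MBZ_A").
#' @slot chain chain identifier.
#' @slot domainSlot "N" or "C".
#' @slot annotation a [DomainAnnotation-class] (possibly empty).
#' @slot atoms as in [StructureModel-class], renumbered to wild-type
#'   numbering and trimmed to the domain span.
#' @slot mutations data.frame(wt, pos, observed): differences from the
#'   wild-type sequence found during renumbering.
#' @export
setClass("DomainStructure",
  representation(parent = "character", chain = "character",
    domainSlot = "character", annotation = "DomainAnnotation",
    atoms = "data.frame", mutations = "data.frame"))

setValidity("DomainStructure", function(object) {
  res <- unique(object@atoms$resno)
  if (anyDuplicated(paste(object@atoms$resno, object@atoms$elety)))
    return("duplicated atom (residue, atom-name) pair")
  TRUE
})

#' SuperpositionResult: one rigid-body overlay
#'
#' @slot rotation 3x3 orthonormal matrix (determinant +1).
#' @slot translation length-3 numeric, Angstrom.
#' @slot rmsd root-mean-square deviation, Angstrom.
#' @slot nAtoms number of paired atoms.
#' @slot pairedPositions [GenericNumber-class] of the paired generic
#'   positions.
#' @export
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
    rmsd = "numeric", nAtoms = "integer",
    pairedPositions = "GenericNumber"))

setValidity("SuperpositionResult", function(object) {
  if (!all(dim(object@rotation) == c(3L, 3L)))
    return("rotation must be 3x3")
  if (abs(det(object@rotation) - 1) > 1e-9)
    return("rotation determinant must be +1")
  if (object@rmsd < 0) return("rmsd must be non-negative")
  TRUE
})

#' SyntheticFamily: a generated SH2-like alignment with ground truth
#'
#' @slot alignment named character vector of equal-length aligned
#'   sequences.
#' @slot segmentation per-column segment label (NA for loops).
#' @slot numbering data.frame(column, segment, index): the true column
#'   numbering, anchors included.
#' @slot anchors named integer vector: the planted invariant (anchor)
#'   column per numbered segment.
#' @slot annotations named list of [DomainAnnotation-class], the
#'   ground-truth per-record annotations.
#' @slot seed the generator seed.
#' @export
setClass("SyntheticFamily",
  representation(alignment = "character", segmentation = "character",
    numbering = "data.frame", anchors = "integer", annotations = "list",
    seed = "integer"))
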