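#' @include AllClasses.R AllGenerics.R
NULL

## Alternation ordered longest-first so "bBbC" and the aB' aliases win
## over their prefixes under PCRE first-match semantics.
.GN_REGEX <- "^(bBbC|aBp|aB'|aB′|bA|bB|bC|bD|bE|bF|aA|aB)[x.]([0-9]+)$"

#' Parse generic-number labels
#'
#' Labels follow the grammar `<segment>x<index>` (e.g. `bBx50`). A `.`
#' separator is accepted as an alias for `x` on input (`bE.48`), and the
#' STAT helix aB' may be written `aBp` or with a Unicode prime. Output of
#' [formatGenericNumber()] always uses `x` and the ASCII apostrophe.
#'
#' @param label character vector of labels.
#' @return A [GenericNumber-class] of the same length.
#' @examples
#' parseGenericNumber("bBx50")
#' parseGenericNumber(c("bBbCx49", "aBpx50", "bE.48"))
#' @export
parseGenericNumber <- function(label) {
  label <- as.character(label)
  if (!length(label) || any(is.na(label)) || any(!nzchar(label)))
    stop("label must be non-empty text")
  m <- regmatches(label, regexec(.GN_REGEX, label, perl = TRUE))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad))
    stop("malformed generic number label: '", label[which(bad)[1L]], "'")
  seg <- .normalizeSegment(vapply(m, `[`, "", 2L))
  idx <- as.integer(vapply(m, `[`, "", 3L))
  if (any(idx < 1L))
    stop("generic index must be positive in label '",
      label[which(idx < 1L)[1L]], "'")
  GenericNumber(seg, idx)
}

#' Format generic numbers as canonical labels
#'
#' @param gn a [GenericNumber-class].
#' @return character vector; `parseGenericNumber(formatGenericNumber(gn))`
#'   is the identity.
#' @examples
#' formatGenericNumber(GenericNumber("bD", 50))
#' @export
formatGenericNumber <- function(gn) {
  stopifnot(is(gn, "GenericNumber"))
  paste0(gn@segment, "x", gn@index)
}

#' @describeIn GenericNumber-class number of positions held.
#' @param x a GenericNumber.
#' @export
setMethod("length", "GenericNumber", function(x) length(x@segment))

#' @describeIn GenericNumber-class subset positions.
#' @param i index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "GenericNumber", function(x, i, j, ..., drop = TRUE)
  GenericNumber(x@segment[i], x@index[i]))

setMethod("show", "GenericNumber", function(object) {
  cat("GenericNumber of length", length(object), "\n")
  if (length(object))
    cat(" ", paste(formatGenericNumber(object), collapse = " "), "\n")
})

#' @describeIn SchemeDefinition-class segment label of each position.
#' @param gn a GenericNumber.
#' @export
segmentOf <- function(gn) gn@segment

#' @describeIn SchemeDefinition-class integer index of each position.
#' @export
indexOf <- function(gn) gn@index

## ---- scheme resource -----------------------------------------------------

#' Load the bundled scheme definition
#'
#' The scheme ships as a versioned JSON resource inside the package. It
#' defines the common and STAT segment layouts, the eight Sheinerman
#' phosphotyrosine-pocket positions, and the FLVR-motif exception
#' proteins whose bBx50 arginine is replaced by an aromatic residue.
#'
#' @param path optional path to an alternative scheme JSON file.
#' @return A [SchemeDefinition-class].
#' @examples
#' sch <- loadScheme()
#' segmentLayout(sch, "STAT")
#' @export
loadScheme <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "sh2_scheme.json", package = "SH2generic",
      mustWork = TRUE)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(d) data.frame(name = .normalizeSegment(d$name),
    kind = d$kind, rank = as.integer(d$rank))
  new("SchemeDefinition",
    segmentsCommon = mk(js$segments_common),
    segmentsStat = mk(js$segments_stat),
    sheinerman = parseGenericNumber(js$sheinerman_positions),
    flvrExceptions = as.character(js$flvr_exception_proteins),
    anchorIndex = as.integer(js$anchor_index),
    version = as.character(js$version))
}

#' The eight Sheinerman phosphotyrosine-pocket positions
#'
#' The pY-pocket residue group (including the critical anchoring arginine
#' at bBx50) primarily responsible for phosphotyrosine binding, in layout
#' order.
#'
#' @param scheme a [SchemeDefinition-class], default the bundled scheme.
#' @return A [GenericNumber-class] of length 8.
#' @export
sheinermanSet <- function(scheme = loadScheme()) {
  stopifnot(is(scheme, "SchemeDefinition"))
  scheme@sheinerman
}

#' Ordered numbered segments of a layout variant
#'
#' @param scheme a [SchemeDefinition-class].
#' @param variant `"common"` (bA aA bB bBbC bC bD bE bF aB) or `"STAT"`
#'   (bE/bF absent, aB' between bD and aB).
#' @return data.frame with columns `name`, `kind`, `rank`, ordered by
#'   rank.
#' @export
segmentLayout <- function(scheme = loadScheme(),
    variant = c("common", "STAT")) {
  variant <- match.arg(variant)
  d <- if (variant == "common") scheme@segmentsCommon else
    scheme@segmentsStat
  d[order(d$rank), , drop = FALSE]
}

setMethod("show", "SchemeDefinition", function(object) {
  cat("SchemeDefinition (version ", object@version, ")\n", sep = "")
  cat("  common layout:",
    paste(segmentLayout(object, "common")$name, collapse = " "), "\n")
  cat("  STAT layout:  ",
    paste(segmentLayout(object, "STAT")$name, collapse = " "), "\n")
  cat("  Sheinerman set:",
    paste(formatGenericNumber(object@sheinerman), collapse = " "), "\n")
  cat("  FLVR exceptions:",
    paste(object@flvrExceptions, collapse = ", "), "\n")
})

## ---- annotation accessors and resolution ---------------------------------

#' @rdname proteinId
#' @param x a [DomainAnnotation-class].
#' @export
setMethod("proteinId", "DomainAnnotation", function(x) x@proteinId)

#' @rdname positionMap
#' @param x a [DomainAnnotation-class].
#' @export
setMethod("positionMap", "DomainAnnotation", function(x) x@positionMap)

#' @describeIn DomainAnnotation-class one-letter residue at a wild-type
#'   residue number, or NA when no sequence is attached.
#' @param ann a DomainAnnotation.
#' @param residue residue number.
#' @export
residueAt <- function(ann, residue) {
  if (is.na(ann@sequence)) return(NA_character_)
  p <- residue - ann@seqOffset + 1L
  if (p < 1L || p > nchar(ann@sequence)) return(NA_character_)
  substr(ann@sequence, p, p)
}

setMethod("show", "DomainAnnotation", function(object) {
  cat("DomainAnnotation for ", object@proteinId, " (", object@domainSlot,
    "-terminal domain, ", object@layout, " layout)\n", sep = "")
  cat("  ", nrow(object@positionMap), " numbered positions in segments: ",
    paste(unique(object@positionMap$segment), collapse = " "), "\n",
    sep = "")
})

#' @rdname resolvePosition
#' @export
setMethod("resolvePosition", signature("DomainAnnotation", "GenericNumber"),
  function(ann, gn) {
    pm <- ann@positionMap
    out <- integer(length(gn))
    for (k in seq_along(gn)) {
      seg <- gn@segment[k]
      sub <- pm[pm$segment == seg, , drop = FALSE]
      if (!nrow(sub))
        stop("segment ", seg, " is not annotated for ", ann@proteinId)
      hit <- sub$residue[sub$index == gn@index[k]]
      if (!length(hit))
        stop("index ", gn@index[k], " outside the declared span of ",
          seg, " (", min(sub$index), "..", max(sub$index), ") for ",
          ann@proteinId)
      out[k] <- hit
    }
    out
  })

#' @rdname resolvePosition
#' @export
setMethod("resolvePosition", signature("DomainAnnotation", "character"),
  function(ann, gn) resolvePosition(ann, parseGenericNumber(gn)))

#' @rdname assignPosition
#' @export
setMethod("assignPosition", signature("DomainAnnotation", "numeric"),
  function(ann, residue) {
    residue <- as.integer(residue)
    stopifnot(length(residue) == 1L)
    pm <- ann@positionMap
    lo <- min(pm$residue)
    hi <- max(pm$residue)
    if (!is.na(ann@sequence)) {
      lo <- min(lo, ann@seqOffset)
      hi <- max(hi, ann@seqOffset + nchar(ann@sequence) - 1L)
    }
    if (residue < lo || residue > hi)
      stop("residue ", residue, " outside the domain range ", lo, "..", hi)
    hit <- which(pm$residue == residue)
    if (!length(hit)) return(NULL)
    GenericNumber(pm$segment[hit[1L]], pm$index[hit[1L]])
  })

## ---- annotation validation -----------------------------------------------

#' Validate a domain annotation against the scheme
#'
#' Returns findings rather than raising conditions. Structural problems
#' (overlapping or non-monotone segments, duplicated residues) yield
#' `error` findings. A non-arginine residue at bBx50 yields a `warning`
#' finding — the FLVR-motif arginine is (almost) invariant — unless the
#' protein is on the scheme's exception list (RIN2, TYK2, SH2D5), whose
#' domains carry an aromatic residue there and recognise acidic residues
#' instead of phosphotyrosine.
#'
#' @param ann a [DomainAnnotation-class], ideally carrying a sequence.
#' @param scheme a [SchemeDefinition-class].
#' @return data.frame with columns `level` ("error"/"warning") and
#'   `message`; zero rows when the annotation is clean.
#' @export
validateAnnotation <- function(ann, scheme = loadScheme()) {
  stopifnot(is(ann, "DomainAnnotation"), is(scheme, "SchemeDefinition"))
  findings <- data.frame(level = character(), message = character())
  add <- function(level, message) rbind(findings,
    data.frame(level = level, message = message))
  for (msg in .annotationErrors(ann))
    findings <- add("error", msg)
  ## overlap across segments: residue intervals must not intersect
  pm <- ann@positionMap
  segs <- unique(pm$segment)
  if (length(segs) > 1L) {
    rng <- t(vapply(segs, function(s)
      range(pm$residue[pm$segment == s]), numeric(2)))
    ord <- order(rng[, 1L])
    for (k in seq_len(length(segs) - 1L)) {
      a <- ord[k]; b <- ord[k + 1L]
      if (rng[b, 1L] <= rng[a, 2L])
        findings <- add("error", paste0("segments ", segs[a], " and ",
          segs[b], " overlap in residue numbers"))
    }
  }
  ## FLVR arginine check at bBx50
  if ("bB" %in% pm$segment && .ANCHOR_INDEX %in% pm$index[pm$segment == "bB"]) {
    res <- pm$residue[pm$segment == "bB" & pm$index == .ANCHOR_INDEX]
    aa <- residueAt(ann, res)
    if (!is.na(aa) && aa != "R" &&
        !(ann@proteinId %in% scheme@flvrExceptions))
      findings <- add("warning", paste0("residue at bBx50 (", res,
        ") is ", aa, ", not the FLVR-motif arginine"))
  }
  findings
}
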