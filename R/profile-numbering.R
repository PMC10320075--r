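#' @include scheme.R
NULL

## Canonical in-memory alignment form: character matrix, rows = records
## (unique ids as rownames), "-" for gaps. Accepts a named character
## vector, an AAStringSet/AAMultipleAlignment, or a matrix.
.alnMatrix <- function(aln) {
  if (is(aln, "AAMultipleAlignment")) aln <- as(aln, "AAStringSet")
  if (is(aln, "XStringSet")) {
    ids <- names(aln)
    aln <- as.character(aln)
    names(aln) <- ids
  }
  if (is.matrix(aln)) {
    m <- aln
  } else {
    aln <- structure(as.character(aln), names = names(aln))
    if (is.null(names(aln)) || anyDuplicated(names(aln)))
      stop("alignment records must carry unique ids")
    w <- nchar(aln)
    if (length(unique(w)) != 1L)
      stop("aligned sequences must all have equal length")
    m <- do.call(rbind, strsplit(toupper(aln), ""))
    rownames(m) <- names(aln)
  }
  m[m == "."] <- "-"
  m
}

.ungap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Per-column conservation of an alignment
#'
#' Conservation is the modal non-gap residue frequency among the non-gap
#' entries of the column; a column of gaps scores 0. Scores lie in
#' \[0, 1\] and are invariant to record order.
#'
#' @param aln an alignment (named character vector of equal-length
#'   aligned sequences, an `AAStringSet`, or a character matrix).
#' @param column integer column index (vectorised).
#' @return numeric vector of scores in \[0, 1\].
#' @export
columnConservation <- function(aln, column) {
  m <- .alnMatrix(aln)
  column <- as.integer(column)
  if (any(column < 1L | column > ncol(m)))
    stop("column index out of range 1..", ncol(m))
  vapply(column, function(j) {
    x <- m[, j]
    x <- x[x != "-"]
    if (!length(x)) return(0)
    max(table(x)) / length(x)
  }, numeric(1))
}

#' Select the x50 anchor column of a segment
#'
#' The anchor is the most conserved column of the segment's column range;
#' ties are broken by the leftmost column. Columns with gap fraction
#' above 0.5 are ineligible, unless every column of the range is.
#'
#' @param aln an alignment.
#' @param segCols contiguous integer vector of column indices.
#' @return the selected column index.
#' @export
selectAnchorColumn <- function(aln, segCols) {
  segCols <- as.integer(segCols)
  if (!length(segCols)) stop("empty segment column range")
  m <- .alnMatrix(aln)
  gapFrac <- vapply(segCols, function(j) mean(m[, j] == "-"), numeric(1))
  eligible <- gapFrac <= 0.5
  if (!any(eligible)) eligible <- rep(TRUE, length(segCols))
  cons <- columnConservation(m, segCols)
  cons[!eligible] <- -Inf
  segCols[which.max(cons)]
}

#' Number the columns of one segment
#'
#' The anchor column receives index 50; columns left and right of it are
#' numbered sequentially (anchor - k maps to 50 - k). The bBbC turn is
#' special-cased: its two columns always receive the fixed indices 49 and
#' 50, regardless of the anchor argument.
#'
#' @param segCols contiguous integer vector of column indices.
#' @param anchor anchor column (must lie in `segCols`); ignored for
#'   `seg = "bBbC"`.
#' @param seg segment label.
#' @return data.frame with columns `column`, `segment`, `index`.
#' @export
numberSegmentColumns <- function(segCols, anchor, seg) {
  segCols <- sort(as.integer(segCols))
  seg <- .normalizeSegment(seg)
  if (seg == "bBbC") {
    if (length(segCols) != 2L)
      stop("the bBbC turn must span exactly 2 columns, got ",
        length(segCols))
    return(data.frame(column = segCols, segment = seg, index = c(49L, 50L)))
  }
  if (!anchor %in% segCols)
    stop("anchor column ", anchor, " not inside the segment range")
  data.frame(column = segCols, segment = seg,
    index = .ANCHOR_INDEX + segCols - as.integer(anchor))
}

## Check a per-column segmentation: labeled columns of each segment form
## one contiguous block, block order follows the layout order.
.checkSegmentation <- function(labels, ncolumns, scheme) {
  labels <- .normalizeSegment(as.character(labels))
  if (length(labels) != ncolumns)
    stop("segmentation length (", length(labels),
      ") does not match alignment width (", ncolumns, ")")
  present <- unique(labels[!is.na(labels)])
  bad <- setdiff(present, .SEGMENTS)
  if (length(bad))
    stop("unknown segment label(s): ", paste(bad, collapse = ", "))
  variant <- if ("aB'" %in% present) "STAT" else "common"
  if (variant == "STAT" && any(c("bE", "bF") %in% present))
    stop("segmentation mixes the STAT helix aB' with bE/bF strands")
  layout <- segmentLayout(scheme, variant)$name
  blocks <- rle(ifelse(is.na(labels), "<loop>", labels))
  segBlocks <- blocks$values[blocks$values != "<loop>"]
  if (anyDuplicated(segBlocks))
    stop("segment ", segBlocks[duplicated(segBlocks)][1L],
      " forms more than one column block")
  if (is.unsorted(match(segBlocks, layout)))
    stop("segment blocks do not follow the ", variant, " layout order")
  labels
}

#' Derive column numbering and per-record annotations from an alignment
#'
#' For each segment block the anchor column is selected by conservation
#' ([selectAnchorColumn()]) and the block is numbered sequentially around
#' it ([numberSegmentColumns()]). Numbers are then propagated to every
#' record by column: each non-gap residue in a numbered column receives
#' that column's generic number, and a record gapped at a numbered column
#' simply lacks that number. Segments with no internal gaps for a record
#' are marked contiguous in its annotation. Residue numbers are 1-based
#' positions in each record's ungapped sequence.
#'
#' @param aln an alignment.
#' @param segmentation per-column segment label, `NA` for unnumbered
#'   (loop) columns; see [readSegmentation()].
#' @param scheme a [SchemeDefinition-class].
#' @return list with elements `numbering` (data.frame column, segment,
#'   index) and `annotations` (named list of
#'   [DomainAnnotation-class], one per record).
#' @export
propagate <- function(aln, segmentation, scheme = loadScheme()) {
  m <- .alnMatrix(aln)
  labels <- .checkSegmentation(segmentation, ncol(m), scheme)
  variant <- if ("aB'" %in% labels[!is.na(labels)]) "STAT" else "common"
  numbering <- NULL
  for (seg in unique(labels[!is.na(labels)])) {
    cols <- which(!is.na(labels) & labels == seg)
    anchor <- if (seg == "bBbC") cols[1L] else selectAnchorColumn(m, cols)
    numbering <- rbind(numbering, numberSegmentColumns(cols, anchor, seg))
  }
  numbering <- numbering[order(numbering$column), , drop = FALSE]
  rownames(numbering) <- NULL
  anns <- lapply(rownames(m), function(id) {
    row <- m[id, ]
    resno <- cumsum(row != "-")      # ungapped position at each column
    keep <- numbering$column[row[numbering$column] != "-"]
    pm <- numbering[numbering$column %in% keep, c("segment", "index")]
    pm$residue <- resno[keep]
    contig <- vapply(unique(numbering$segment), function(seg) {
      cols <- numbering$column[numbering$segment == seg]
      all(row[cols] != "-")
    }, logical(1))
    DomainAnnotation(id, layout = variant, positionMap = pm,
      contiguous = names(contig)[contig], sequence = .ungap(paste(row,
        collapse = "")), seqOffset = 1L)
  })
  names(anns) <- rownames(m)
  list(numbering = numbering, annotations = anns)
}

#' Annotate a new sequence against a numbered alignment
#'
#' The sequence is globally aligned (substitution-matrix scored, affine
#' gaps, free end gaps) to the most similar alignment record; column
#' numbers are transferred through the pairwise alignment. A best
#' pairwise identity below `minIdentity` is refused.
#'
#' @param seq one-letter amino-acid string (a plausible SH2 domain,
#'   `minLen`..`maxLen` residues).
#' @param aln the numbered alignment.
#' @param numbering data.frame(column, segment, index) as produced by
#'   [propagate()].
#' @param proteinId identifier for the returned annotation.
#' @param offset residue number of the first character of `seq`
#'   (default 1); use this when `seq` is a domain cut from a longer
#'   protein, e.g. 580 for a STAT5B SH2 construct.
#' @param substitutionMatrix,gapOpening,gapExtension pairwise-alignment
#'   scoring (defaults BLOSUM62, 11, 1).
#' @param minIdentity refusal floor on pairwise identity (default 0.25).
#' @param minLen,maxLen plausibility bounds on sequence length.
#' @return A [DomainAnnotation-class] for `seq`.
#' @export
numberNewSequence <- function(seq, aln, numbering, proteinId = "query",
    offset = 1L, substitutionMatrix = "BLOSUM62", gapOpening = 11,
    gapExtension = 1, minIdentity = 0.25, minLen = 60L, maxLen = 160L) {
  seq <- toupper(.ungap(as.character(seq)))
  if (nchar(seq) < minLen || nchar(seq) > maxLen)
    stop("sequence length ", nchar(seq), " outside the plausible SH2 ",
      "domain range ", minLen, "..", maxLen)
  m <- .alnMatrix(aln)
  subMat <- .substitutionMatrix(substitutionMatrix)
  templates <- apply(m, 1L, function(r) paste(r[r != "-"], collapse = ""))
  pas <- lapply(templates, function(t)
    Biostrings::pairwiseAlignment(Biostrings::AAString(seq),
      Biostrings::AAString(t), substitutionMatrix = subMat,
      gapOpening = gapOpening, gapExtension = gapExtension,
      type = "overlap"))
  best <- which.max(vapply(pas, Biostrings::score, numeric(1)))
  pa <- pas[[best]]
  ident <- Biostrings::nmatch(pa) /
    min(nchar(seq), nchar(templates[best]))
  if (ident < minIdentity)
    stop("best pairwise identity ", sprintf("%.3f", ident),
      " (to record ", rownames(m)[best], ") is below the floor ",
      minIdentity, "; refusing to number")
  map <- .alignmentMap(pa)          # seq position -> template position
  tmplRow <- m[best, ]
  tmplPos <- cumsum(tmplRow != "-") # column -> template ungapped position
  variant <- if ("aB'" %in% numbering$segment) "STAT" else "common"
  pm <- NULL
  contig <- character()
  for (seg in unique(numbering$segment)) {
    segNum <- numbering[numbering$segment == seg, , drop = FALSE]
    rows <- NULL
    for (k in seq_len(nrow(segNum))) {
      col <- segNum$column[k]
      if (tmplRow[col] == "-") next
      t <- tmplPos[col]
      q <- map$query[match(t, map$template)]
      if (is.na(q)) next
      rows <- rbind(rows, data.frame(segment = seg, index = segNum$index[k],
        residue = q + as.integer(offset) - 1L))
    }
    if (is.null(rows)) next
    pm <- rbind(pm, rows)
    if (nrow(rows) == nrow(segNum) &&
        all(diff(rows$residue) == diff(rows$index)))
      contig <- c(contig, seg)
  }
  if (is.null(pm))
    stop("no numbered position could be transferred to the sequence")
  DomainAnnotation(proteinId, layout = variant, positionMap = pm,
    contiguous = contig, sequence = seq, seqOffset = as.integer(offset))
}

.substitutionMatrix <- function(x) {
  if (is.matrix(x)) return(x)
  e <- new.env()
  utils::data(list = x, package = "Biostrings", envir = e)
  get(x, envir = e)
}

## Position map of an ungapped-pattern/ungapped-subject pairwise
## alignment: data.frame(query, template) of matched positions.
.alignmentMap <- function(pa) {
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  qp <- cumsum(p != "-")
  sp <- cumsum(s != "-")
  keep <- p != "-" & s != "-"
  data.frame(query = qp[keep], template = sp[keep])
}

#' Restrict an alignment to its numbered columns
#'
#' @param aln an alignment.
#' @param numbering data.frame(column, segment, index); must be
#'   non-empty.
#' @return named character vector: the sub-alignment over numbered
#'   columns, column order preserved.
#' @export
numberedSubalignment <- function(aln, numbering) {
  if (is.null(numbering) || !nrow(numbering))
    stop("numbering is empty; nothing to restrict to")
  m <- .alnMatrix(aln)
  cols <- sort(unique(as.integer(numbering$column)))
  sub <- m[, cols, drop = FALSE]
  out <- apply(sub, 1L, paste, collapse = "")
  names(out) <- rownames(m)
  out
}

## ---- file formats --------------------------------------------------------

#' Read an aligned FASTA file
#'
#' @param file path to an aligned FASTA file.
#' @return named character vector of aligned sequences.
#' @export
readAlignmentFasta <- function(file) {
  s <- Biostrings::readAAStringSet(file)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  .alnMatrix(out)  # validates widths/ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param file output path.
#' @export
writeFasta <- function(seqs, file) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(unlist(seqs)), filepath = file)
  invisible(file)
}

#' Read a column segmentation file
#'
#' Two whitespace-separated columns: `column_index`, `segment_label`.
#' Columns not listed are unnumbered (loop) columns.
#'
#' @param file path.
#' @param ncolumns alignment width.
#' @return character vector of length `ncolumns` with NA for loops.
#' @export
readSegmentation <- function(file, ncolumns) {
  d <- utils::read.table(file, header = FALSE, col.names = c("column",
    "segment"), colClasses = c("integer", "character"))
  labels <- rep(NA_character_, ncolumns)
  if (any(d$column < 1L | d$column > ncolumns))
    stop("segmentation column index outside 1..", ncolumns)
  labels[d$column] <- .normalizeSegment(d$segment)
  labels
}
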