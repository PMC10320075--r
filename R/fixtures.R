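#' @include profile-numbering.R structure-io.R
NULL

.AA20 <- names(.AA1TO3)

## Template geometry of the synthetic family: common-layout segment
## lengths and the anchor's offset within each segment. aA (x43..x52),
## bB (x46..x52) and bD (x47..x52) honour the STAT5B index arithmetic,
## so every Sheinerman position exists; bE's anchor sits at its third
## position, so the strand begins at x48 as in the SHP2 N-domain.
.FAM_SEGMENTS <- data.frame(
  name = c("bA", "aA", "bB", "bBbC", "bC", "bD", "bE", "bF", "aB"),
  len = c(5L, 10L, 7L, 2L, 6L, 6L, 4L, 3L, 10L),
  anchorAt = c(3L, 8L, 5L, 1L, 3L, 4L, 3L, 2L, 5L))
.FAM_LOOP <- 3L   # loop columns between consecutive segments

## Run code under a seeded RNG without disturbing the caller's stream.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic SH2-like sequence family with known ground truth
#'
#' Builds a template over the common segment layout, plants one
#' invariant column per numbered segment (the x50 anchor; x49 for the
#' two-column bBbC turn), and derives each record by mutating the
#' remaining columns independently at `mutationRate`. When the i.i.d.
#' draw leaves a non-anchor numbered column untouched in every record, a
#' seed-determined record is substituted there, so the planted anchor is
#' always the unique invariant column of its segment — the property the
#' fixture exists to exhibit. Gaps are planted only in unnumbered (loop)
#' columns, and only when `mutationRate > 0`.
#'
#' @param nRecords number of records (>= 2).
#' @param mutationRate per-column per-record substitution probability in
#'   \[0, 1\].
#' @param seed integer seed; regeneration with the same arguments is
#'   bit-exact.
#' @param gapRate per-record probability of a deletion in each loop
#'   block (default 0.25).
#' @return A [SyntheticFamily-class].
#' @export
makeSyntheticFamily <- function(nRecords = 20L, mutationRate = 0.1,
    seed = 1L, gapRate = 0.25) {
  nRecords <- as.integer(nRecords)
  if (is.na(nRecords) || nRecords < 2L)
    stop("nRecords must be an integer >= 2")
  if (mutationRate < 0 || mutationRate > 1)
    stop("mutationRate must lie in [0, 1]")
  segs <- .FAM_SEGMENTS
  labels <- c()
  for (k in seq_len(nrow(segs))) {
    labels <- c(labels, rep(NA_character_, .FAM_LOOP),
      rep(segs$name[k], segs$len[k]))
  }
  labels <- c(labels, rep(NA_character_, .FAM_LOOP))
  width <- length(labels)
  anchorCols <- integer(nrow(segs))
  for (k in seq_len(nrow(segs))) {
    cols <- which(!is.na(labels) & labels == segs$name[k])
    anchorCols[k] <- cols[segs$anchorAt[k]]
  }
  names(anchorCols) <- segs$name
  .withSeed(seed, {
    template <- sample(.AA20, width, replace = TRUE)
    m <- matrix(rep(template, each = nRecords), nrow = nRecords)
    if (mutationRate > 0) {
      mutable <- setdiff(seq_len(width), anchorCols)
      numberedMutable <- setdiff(which(!is.na(labels)), anchorCols)
      for (j in mutable) {
        hit <- stats::runif(nRecords) < mutationRate
        if (!any(hit) && j %in% numberedMutable)
          hit[sample.int(nRecords, 1L)] <- TRUE
        if (any(hit))
          m[hit, j] <- vapply(which(hit), function(i)
            sample(setdiff(.AA20, template[j]), 1L), "")
      }
      ## occasional loop-region deletions (gap characters)
      loopBlocks <- split(which(is.na(labels)),
        cumsum(c(1, diff(which(is.na(labels)))) != 1))
      for (i in seq_len(nRecords)) for (blk in loopBlocks) {
        if (stats::runif(1) < gapRate) {
          k <- sample.int(min(2L, length(blk)), 1L)
          m[i, blk[seq_len(k)]] <- "-"
        }
      }
    }
    rownames(m) <- sprintf("syn%02d", seq_len(nRecords))
    aln <- apply(m, 1L, paste, collapse = "")
    ## ground truth, computed from column semantics directly
    numbering <- NULL
    for (k in seq_len(nrow(segs))) {
      cols <- which(!is.na(labels) & labels == segs$name[k])
      idx <- if (segs$name[k] == "bBbC") c(49L, 50L) else
        .ANCHOR_INDEX + cols - anchorCols[k]
      numbering <- rbind(numbering, data.frame(column = cols,
        segment = segs$name[k], index = idx))
    }
    numbering <- numbering[order(numbering$column), , drop = FALSE]
    rownames(numbering) <- NULL
    anns <- lapply(rownames(m), function(id) {
      row <- m[id, ]
      resno <- cumsum(row != "-")
      keep <- numbering$column[row[numbering$column] != "-"]
      pm <- numbering[numbering$column %in% keep, c("segment", "index")]
      pm$residue <- resno[keep]
      DomainAnnotation(id, layout = "common", positionMap = pm,
        contiguous = unique(numbering$segment),
        sequence = .ungap(paste(row, collapse = "")), seqOffset = 1L)
    })
    names(anns) <- rownames(m)
    new("SyntheticFamily", alignment = aln, segmentation = labels,
      numbering = numbering, anchors = anchorCols, annotations = anns,
      seed = as.integer(seed))
  })
}

setMethod("show", "SyntheticFamily", function(object) {
  cat("SyntheticFamily:", length(object@alignment), "records,",
    length(object@segmentation), "columns,",
    nrow(object@numbering), "numbered positions (seed",
    object@seed, ")\n")
})

#' Idealised backbone coordinates for an annotated domain
#'
#' Emits N/CA/C backbone atoms for every numbered position of the
#' annotation, on segment-specific geometry templates (extended-strand
#' and helical traces laid out on a per-segment frame), plus a seeded
#' coordinate jitter of at most `jitter` Angstrom. An optional rigid
#' transform is applied last and recorded in the model metadata, so
#' superposition tests can compare against the known ground truth:
#' with the same seed, the transformed model's coordinates are exactly
#' the rigid transform of the untransformed model's.
#'
#' @param ann a [DomainAnnotation-class] with core-sheet positions.
#' @param rotation 3x3 rotation applied to all coordinates (default
#'   identity).
#' @param translation length-3 translation (default zero).
#' @param seed integer seed for the jitter.
#' @param jitter maximal per-coordinate jitter in Angstrom (default
#'   0.05).
#' @param chain chain identifier (default "A").
#' @return A [StructureModel-class]; `metadata$transform` records the
#'   applied rotation and translation.
#' @export
makeSyntheticDomainStructure <- function(ann, rotation = diag(3),
    translation = c(0, 0, 0), seed = 1L, jitter = 0.05, chain = "A") {
  pm <- positionMap(ann)
  if (!nrow(pm)) stop("annotation carries no numbered positions")
  segRank <- match(pm$segment, .SEGMENTS)
  ## per-segment frame: origin fanned out by rank, direction rotated in
  ## the xy-plane so no two segments are parallel (avoids degeneracy)
  theta <- segRank * 0.7
  ox <- 12 * cos(segRank * 2.2)
  oy <- 12 * sin(segRank * 2.2)
  oz <- 3 * segRank
  step <- ifelse(pm$segment %in% .HELICES, 1.5, 3.4)
  t <- pm$index - .ANCHOR_INDEX
  ca <- cbind(ox + t * step * cos(theta), oy + t * step * sin(theta),
    oz + ifelse(pm$segment %in% .HELICES, 1.2 * sin(100 * pi / 180 * t),
      0.4 * (-1)^t))
  parity <- (-1)^pm$index
  nAt <- ca + cbind(-0.9 * cos(theta) - 0.6 * sin(theta) * parity,
    -0.9 * sin(theta) + 0.6 * cos(theta) * parity, 0.45 * parity)
  cAt <- ca + cbind(0.9 * cos(theta) + 0.55 * sin(theta) * parity,
    0.9 * sin(theta) - 0.55 * cos(theta) * parity, -0.4 * parity)
  nres <- nrow(pm)
  xyz <- rbind(nAt, ca, cAt)[rep(seq_len(nres), each = 3L) +
    c(0L, nres, 2L * nres), , drop = FALSE]
  xyz <- .withSeed(seed, xyz + matrix(stats::runif(length(xyz), -jitter,
    jitter), ncol = 3L))
  xyz <- sweep(xyz %*% t(rotation), 2L, -as.numeric(translation))
  aa <- vapply(pm$residue, function(r) {
    a1 <- residueAt(ann, r)
    if (is.na(a1) || !a1 %in% names(.AA1TO3)) "ALA" else .AA1TO3[[a1]]
  }, "")
  atomsDf <- data.frame(type = "ATOM", eleno = seq_len(3L * nres),
    elety = rep(.BACKBONE, nres), alt = "",
    resid = rep(aa, each = 3L), chain = chain,
    resno = rep(pm$residue, each = 3L), insert = "",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], o = 1, b = 0)
  new("StructureModel", atoms = atomsDf,
    metadata = list(id = paste0("synth_", proteinId(ann)),
      transform = list(rotation = rotation,
        translation = as.numeric(translation)), seed = as.integer(seed)))
}

#' Bundled reference anchor annotations
#'
#' The packaged reference annotations: the STAT5B map (all eight
#' Sheinerman pocket positions, expanded from the printed anchors by
#' sequential within-segment numbering), the partial SHP2 N-terminal
#' domain map (Y62 at bEx48; D61 sits in the unnumbered bDbE blocking
#' loop), and the FLVR-motif exception proteins.
#'
#' @return list with elements `stat5b` and `shp2N`
#'   ([DomainAnnotation-class]) and `flvrExceptions` (character).
#' @examples
#' ba <- bundledAnchors()
#' resolvePosition(ba$stat5b, "bBx50")   # 618
#' resolvePosition(ba$shp2N, "bEx48")    # 62
#' @export
bundledAnchors <- function() {
  path <- system.file("extdata", "bundled_anchors.json",
    package = "SH2generic", mustWork = TRUE)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(e) DomainAnnotation(e$protein_id,
    domainSlot = e$domain_slot, layout = e$layout,
    anchors = data.frame(segment = e$anchors$segment,
      index = e$anchors$index, residue = e$anchors$residue),
    spans = data.frame(segment = e$spans$segment,
      indexMin = e$spans$index_min, indexMax = e$spans$index_max))
  list(stat5b = mk(js$stat5b), shp2N = mk(js$shp2_n),
    flvrExceptions = as.character(js$flvr_exceptions))
}
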