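#' @include structure-io.R
NULL

.CORE_SEGMENTS <- c("bB", "bC", "bD")
.BACKBONE <- c("N", "CA", "C")

## Backbone coordinates of one domain at a set of residue numbers,
## as a data.frame(resno, elety, x, y, z) in (resno, N/CA/C) order.
.backboneAt <- function(ds, resno) {
  a <- atoms(ds)
  a <- a[a$resno %in% resno & a$elety %in% .BACKBONE, , drop = FALSE]
  a <- a[order(match(a$resno, resno), match(a$elety, .BACKBONE)), ,
    drop = FALSE]
  a[, c("resno", "elety", "x", "y", "z")]
}

#' Paired core-beta-sheet coordinates of two domains
#'
#' For every generic position of the core beta-sheet (strands bB, bC,
#' bD) annotated in both domains, collects the backbone atoms (N, CA, C)
#' present in both structures. The sheet is the superposition anchor:
#' after multiple rounds of structural alignment it gives the most
#' reliable overlay across the SH2 family.
#'
#' @param mobile,reference [DomainStructure-class] objects carrying
#'   annotations with bB/bC/bD positions.
#' @return list with matrices `P` (mobile) and `Q` (reference) of equal
#'   dimension, `positions` (the paired [GenericNumber-class]) and
#'   `nAtoms`.
#' @export
coreSheetPairs <- function(mobile, reference) {
  pmM <- positionMap(annotation(mobile))
  pmR <- positionMap(annotation(reference))
  pmM <- pmM[pmM$segment %in% .CORE_SEGMENTS, , drop = FALSE]
  pmR <- pmR[pmR$segment %in% .CORE_SEGMENTS, , drop = FALSE]
  keyM <- paste(pmM$segment, pmM$index)
  keyR <- paste(pmR$segment, pmR$index)
  shared <- intersect(keyM, keyR)
  if (!length(shared))
    stop("no shared core-sheet (bB/bC/bD) positions between the domains")
  pmM <- pmM[match(shared, keyM), ]
  pmR <- pmR[match(shared, keyR), ]
  bbM <- .backboneAt(mobile, pmM$residue)
  bbR <- .backboneAt(reference, pmR$residue)
  ## intersect atom-wise: (position, atom name) present in both
  tagM <- paste(shared[match(bbM$resno, pmM$residue)], bbM$elety)
  tagR <- paste(shared[match(bbR$resno, pmR$residue)], bbR$elety)
  common <- intersect(tagM, tagR)
  if (length(common) < 9L)
    stop("insufficient anchor: only ", length(common),
      " paired core-sheet backbone atoms (need >= 9)")
  bbM <- bbM[match(common, tagM), ]
  bbR <- bbR[match(common, tagR), ]
  posKeys <- unique(sub(" [A-Z]+$", "", common))
  parts <- strsplit(posKeys, " ")
  pos <- GenericNumber(vapply(parts, `[`, "", 1L),
    as.integer(vapply(parts, `[`, "", 2L)))
  list(P = as.matrix(bbM[, c("x", "y", "z")]),
    Q = as.matrix(bbR[, c("x", "y", "z")]),
    positions = pos, nAtoms = length(common))
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimising the RMSD of
#' `R P + t` onto `Q`, by singular value decomposition of the
#' cross-covariance matrix with reflection correction.
#'
#' @param P,Q n x 3 coordinate matrices (n >= 3, non-collinear), rows
#'   paired.
#' @param positions optional [GenericNumber-class] recorded in the
#'   result.
#' @return A [SuperpositionResult-class].
#' @export
kabsch <- function(P, Q, positions = GenericNumber(character(),
    integer())) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3L)
    stop("P and Q must be equally sized n x 3 matrices")
  n <- nrow(P)
  if (n < 3L) stop("at least 3 paired points are required")
  cP <- colMeans(P); cQ <- colMeans(Q)
  Pc <- sweep(P, 2L, cP); Qc <- sweep(Q, 2L, cQ)
  sv <- svd(crossprod(Pc, Pc))
  if (sv$d[2L] <= 1e-8 * max(sv$d[1L], 1e-12))
    stop("degenerate (collinear) coordinates; superposition undefined")
  s <- svd(crossprod(Pc, Qc))      # t(Pc) %*% Qc
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  dev <- Pc %*% t(R) - Qc
  rmsd <- sqrt(sum(dev^2) / n)
  new("SuperpositionResult", rotation = R,
    translation = as.numeric(cQ - R %*% cP), rmsd = rmsd,
    nAtoms = as.integer(n), pairedPositions = positions)
}

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd %.4f A over %d atoms (%d positions)\n",
    object@rmsd, object@nAtoms, length(object@pairedPositions)))
})

#' Apply a rigid transform to a structure's coordinates
#'
#' @param x a [DomainStructure-class] or [StructureModel-class].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation.
#' @return the transformed object.
#' @export
transformStructure <- function(x, rotation, translation) {
  a <- atoms(x)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(rotation)
  xyz <- sweep(xyz, 2L, -as.numeric(translation))
  a$x <- xyz[, 1L]; a$y <- xyz[, 2L]; a$z <- xyz[, 3L]
  x@atoms <- a
  x
}

#' Superpose a batch of domains onto a reference
#'
#' Each domain is superposed on the reference via its core-sheet pairing
#' and transformed into the reference frame. Per-domain failures (e.g.
#' missing core annotations) are collected, not fatal to the batch. The
#' reference itself, if included, superposes with rmsd 0.
#'
#' @param domains list of annotated [DomainStructure-class].
#' @param reference the reference [DomainStructure-class].
#' @return list (same order as `domains`) of lists with elements
#'   `domain` (transformed structure), `result`
#'   ([SuperpositionResult-class]) and `error` (NULL or the failure
#'   message).
#' @export
superposeAll <- function(domains, reference) {
  lapply(domains, function(d) {
    tryCatch({
      pr <- coreSheetPairs(d, reference)
      res <- kabsch(pr$P, pr$Q, pr$positions)
      list(domain = transformStructure(d, res@rotation, res@translation),
        result = res, error = NULL)
    }, error = function(e)
      list(domain = d, result = NULL, error = conditionMessage(e)))
  })
}

#' Export a molecular-viewer session script
#'
#' Emits a plain-text, PyMOL-dialect script that loads each (already
#' transformed) structure, creates one named selection per highlighted
#' generic position (name pattern `gn_<label>`), and shows those
#' selections as sticks — mirroring the on-the-fly sessions used to
#' inspect the Sheinerman pocket across superposed domains.
#'
#' @param domains list of [DomainStructure-class] (already in a common
#'   frame).
#' @param highlight [GenericNumber-class] positions to select, e.g.
#'   `sheinermanSet()`.
#' @param files file names used in the load statements; default
#'   `<parent>.pdb`.
#' @return the script as a single string.
#' @export
exportSessionScript <- function(domains, highlight = sheinermanSet(),
    files = NULL) {
  objNames <- vapply(domains, function(d)
    gsub("[^A-Za-z0-9_.-]", "_", d@parent), "")
  if (is.null(files)) files <- paste0(objNames, ".pdb")
  lines <- paste("load", files, objNames, sep = ", ")
  lines <- sub(", ", " ", lines, fixed = TRUE)  # "load file, name"
  for (k in seq_along(highlight)) {
    gn <- highlight[k]
    label <- formatGenericNumber(gn)
    parts <- character()
    for (j in seq_along(domains)) {
      res <- tryCatch(resolvePosition(annotation(domains[[j]]), gn),
        error = function(e) NULL)
      if (!is.null(res))
        parts <- c(parts, sprintf("(%s and resi %d)", objNames[j], res))
    }
    selName <- paste0("gn_", gsub("'", "p", label))
    if (!length(parts)) {
      lines <- c(lines, paste0("# warning: position ", label,
        " resolvable in no loaded domain"))
    } else {
      lines <- c(lines,
        paste0("select ", selName, ", ", paste(parts, collapse = " or ")),
        paste0("show sticks, ", selName))
    }
  }
  paste(lines, collapse = "\n")
}
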