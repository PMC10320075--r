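#' @include scheme.R
NULL

## 3 -> 1 letter translation, modified residues mapped to their parent
## when mapModified is on (MSE -> M etc.); anything else -> X.
.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L",
  LYS = "K", MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T",
  TRP = "W", TYR = "Y", VAL = "V")
.AA3MOD <- c(MSE = "M", SEP = "S", TPO = "T", PTR = "Y", CSO = "C",
  HYP = "P")
.AA1TO3 <- structure(names(.AA3TO1), names = unname(.AA3TO1))

#' Parse PDB-format coordinates
#'
#' Fixed-column ATOM/HETATM parsing (backed by bio3d). For alternate
#' locations the highest-occupancy conformer is kept, ties resolved in
#' favour of alt-loc "A"; insertion-coded residues are retained as
#' distinct residues. Waters are always dropped; other heteroatoms are
#' dropped unless `keepHetero`.
#'
#' @param x PDB-format text (a single string or character vector of
#'   lines) or a path to a PDB file.
#' @param keepHetero keep non-water HETATM records (default FALSE).
#' @param id entry identifier stored in the metadata (defaults to the
#'   file name, or "unknown" for text input).
#' @return A [StructureModel-class].
#' @export
readStructure <- function(x, keepHetero = FALSE, id = NULL) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    if (is.null(id)) id <- sub("\\.pdb$", "", basename(x))
    lines <- readLines(x)
  } else {
    if (is.null(id)) id <- "unknown"
    lines <- unlist(strsplit(x, "\n", fixed = TRUE))
  }
  isAtom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(grepl("^ATOM  ", lines)))
    stop("no ATOM records found in the input")
  for (i in which(isAtom)) {
    ln <- lines[i]
    if (nchar(ln) < 54L)
      stop("malformed fixed-width ATOM record at line ", i,
        " (shorter than 54 columns)")
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
      substr(ln, 39, 46), substr(ln, 47, 54))))
    if (any(is.na(coords)))
      stop("malformed coordinate field at line ", i)
    if (is.na(suppressWarnings(as.integer(substr(ln, 23, 26)))))
      stop("malformed residue number at line ", i)
  }
  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f))
  writeLines(lines, f)
  pdb <- bio3d::read.pdb(f, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  a$alt[is.na(a$alt)] <- ""
  a$insert[is.na(a$insert)] <- ""
  a$chain[is.na(a$chain)] <- ""
  a$o[is.na(a$o)] <- 1
  a$b[is.na(a$b)] <- 0
  a <- a[a$resid != "HOH", , drop = FALSE]
  if (!keepHetero) a <- a[a$type == "ATOM", , drop = FALSE]
  ## altloc policy: per (chain, residue, atom name) keep the
  ## highest-occupancy conformer; ties prefer alt "A".
  key <- paste(a$chain, a$resno, a$insert, a$elety)
  ord <- order(key, -a$o, a$alt != "A", a$alt)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(key[ord]), , drop = FALSE]
  a <- a[order(match(a$eleno, pdb$atom$eleno)), , drop = FALSE]
  rownames(a) <- NULL
  cols <- c("type", "eleno", "elety", "alt", "resid", "chain", "resno",
    "insert", "x", "y", "z", "o", "b")
  new("StructureModel", atoms = a[, cols], metadata = list(id = id))
}

#' @rdname atoms
#' @param x a [StructureModel-class] or [DomainStructure-class].
#' @export
setMethod("atoms", "StructureModel", function(x) x@atoms)

#' @rdname atoms
#' @export
setMethod("atoms", "DomainStructure", function(x) x@atoms)

#' @rdname annotation-accessor
#' @param x a [DomainStructure-class].
#' @export
setMethod("annotation", "DomainStructure", function(x) x@annotation)

#' @rdname mutations
#' @param x a [DomainStructure-class].
#' @export
setMethod("mutations", "DomainStructure", function(x) x@mutations)

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat("StructureModel", object@metadata$id %||% "", "with", nrow(a),
    "atoms,", length(unique(paste(a$chain, a$resno, a$insert))),
    "residues, chains:", paste(unique(a$chain), collapse = " "), "\n")
})

setMethod("show", "DomainStructure", function(object) {
  cat("DomainStructure ", object@parent, " (", object@domainSlot,
    "-terminal SH2), ", nrow(object@atoms), " atoms, residues ",
    min(object@atoms$resno), "..", max(object@atoms$resno), sep = "")
  if (nrow(object@mutations))
    cat(", mutations: ", paste0(object@mutations$wt,
      object@mutations$pos, object@mutations$observed, collapse = " "))
  cat("\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a

## Distinct residues of one chain, in file order.
.chainResidues <- function(model, chain) {
  a <- model@atoms
  a <- a[a$chain == chain, , drop = FALSE]
  if (!nrow(a))
    stop("chain '", chain, "' not present in the structure")
  key <- paste(a$resno, a$insert)
  a[!duplicated(key), c("resno", "insert", "resid"), drop = FALSE]
}

#' One-letter sequence of a chain
#'
#' @param model a [StructureModel-class].
#' @param chain chain identifier.
#' @param mapModified translate common modified residues (MSE, SEP, TPO,
#'   PTR, ...) to their parent amino acid (default TRUE); unknown
#'   residues become "X".
#' @return list with `sequence` (string), `resno` and `insert`
#'   (parallel vectors of residue numbers / insertion codes).
#' @export
chainSequence <- function(model, chain, mapModified = TRUE) {
  res <- .chainResidues(model, chain)
  tab <- if (mapModified) c(.AA3TO1, .AA3MOD) else .AA3TO1
  aa <- unname(tab[res$resid])
  aa[is.na(aa)] <- "X"
  list(sequence = paste(aa, collapse = ""), resno = res$resno,
    insert = res$insert)
}

#' Renumber a chain to wild-type numbering
#'
#' Aligns the chain's observed sequence to the wild-type sequence
#' (global, free end gaps, BLOSUM62 11/1) and replaces author residue
#' numbers by wild-type numbers (`wt position + wtOffset - 1`).
#' Insertion codes are eliminated by the renumbering. Aligned positions
#' whose residues differ are recorded as mutations; structure residues
#' that align to no wild-type position are removed from the chain and
#' reported.
#'
#' @param model a [StructureModel-class].
#' @param chain chain to renumber.
#' @param wt wild-type one-letter sequence (the domain window).
#' @param wtOffset residue number of the first wild-type character
#'   (default 1).
#' @param minIdentity refusal floor on alignment identity (default 0.9).
#' @return list with `model` (renumbered [StructureModel-class]),
#'   `mutations` (data.frame wt, pos, observed) and `removed`
#'   (data.frame of trimmed author residues).
#' @export
renumberToWildtype <- function(model, chain, wt, wtOffset = 1L,
    minIdentity = 0.9) {
  wt <- toupper(.ungap(as.character(wt)))
  cs <- chainSequence(model, chain)
  pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(cs$sequence),
    Biostrings::AAString(wt),
    substitutionMatrix = .substitutionMatrix("BLOSUM62"),
    gapOpening = 11, gapExtension = 1, type = "overlap")
  ## identity over the shorter sequence, so a short high-scoring local
  ## overlap between unrelated sequences cannot pass the floor
  ident <- Biostrings::nmatch(pa) / min(nchar(cs$sequence), nchar(wt))
  if (ident < minIdentity)
    stop("chain/wild-type identity ", sprintf("%.3f", ident),
      " is below the floor ", minIdentity)
  map <- .alignmentMap(pa)  # query = structure residue rank, template = wt pos
  newno <- map$template + as.integer(wtOffset) - 1L
  obs <- strsplit(cs$sequence, "")[[1L]][map$query]
  wtres <- strsplit(wt, "")[[1L]][map$template]
  diffs <- which(obs != wtres)
  muts <- data.frame(wt = wtres[diffs], pos = newno[diffs],
    observed = obs[diffs], stringsAsFactors = FALSE)
  a <- model@atoms
  inChain <- a$chain == chain
  key <- paste(a$resno, a$insert)[inChain]
  resKey <- paste(cs$resno, cs$insert)
  rank <- match(key, resKey)              # residue rank within the chain
  newForRank <- rep(NA_integer_, length(resKey))
  newForRank[map$query] <- newno
  mapped <- newForRank[rank]
  removed <- data.frame(resno = cs$resno, insert = cs$insert)[
    is.na(newForRank), , drop = FALSE]
  keep <- !inChain
  keep[inChain] <- !is.na(mapped)
  a$resno[inChain] <- mapped
  a$insert[inChain] <- ""
  a <- a[keep, , drop = FALSE]
  rownames(a) <- NULL
  out <- model
  out@atoms <- a
  list(model = out, mutations = muts, removed = removed)
}

#' Split a structure into single-SH2-domain structures
#'
#' One [DomainStructure-class] per boundary row; residues outside
#' `[start, end]` are removed. Dual-domain chains yield two entries
#' tagged N and C; the same domain present in several chains yields one
#' entry per chain.
#'
#' @param model a (renumbered) [StructureModel-class].
#' @param boundaries data.frame with columns `chain`, `slot` ("N"/"C"),
#'   `start`, `end` (inclusive wild-type residue numbers).
#' @param annotations optional named list of
#'   [DomainAnnotation-class] keyed by `"<chain>:<slot>"` or `"<slot>"`,
#'   attached to the corresponding output.
#' @param mutations optional data.frame(wt, pos, observed) from
#'   [renumberToWildtype()]; rows within each span are attached.
#' @return list of [DomainStructure-class].
#' @export
extractDomains <- function(model, boundaries, annotations = NULL,
    mutations = NULL) {
  id <- model@metadata$id %||% "unknown"
  emptyAnn <- DomainAnnotation("unannotated", positionMap = data.frame(
    segment = character(), index = integer(), residue = integer()),
    check = FALSE)
  lapply(seq_len(nrow(boundaries)), function(k) {
    b <- boundaries[k, ]
    a <- model@atoms
    a <- a[a$chain == b$chain & a$resno >= b$start & a$resno <= b$end, ,
      drop = FALSE]
    if (!nrow(a))
      stop("empty selection for chain ", b$chain, " ", b$start, "..",
        b$end)
    rownames(a) <- NULL
    ann <- emptyAnn
    if (!is.null(annotations)) {
      hit <- annotations[[paste0(b$chain, ":", b$slot)]] %||%
        annotations[[as.character(b$slot)]]
      if (!is.null(hit)) ann <- hit
    }
    mut <- data.frame(wt = character(), pos = integer(),
      observed = character())
    if (!is.null(mutations) && nrow(mutations))
      mut <- mutations[mutations$pos >= b$start & mutations$pos <= b$end, ,
        drop = FALSE]
    new("DomainStructure", parent = paste0(id, "_", b$chain),
      chain = as.character(b$chain), domainSlot = as.character(b$slot),
      annotation = ann, atoms = a, mutations = mut)
  })
}

#' Read a domain-boundary file
#'
#' Tab-separated columns: entry, chain, slot, start, end.
#'
#' @param file path.
#' @return data.frame(entry, chain, slot, start, end).
#' @export
readBoundaries <- function(file) {
  utils::read.table(file, header = FALSE, sep = "\t",
    col.names = c("entry", "chain", "slot", "start", "end"),
    colClasses = c("character", "character", "character", "integer",
      "integer"))
}

#' Write a structure in PDB format
#'
#' Fixed-width ATOM records; reading the output back with
#' [readStructure()] reproduces atoms, numbering and coordinates (3
#' decimals) exactly.
#'
#' @param x a [DomainStructure-class] or [StructureModel-class].
#' @param file output path, or NULL to return the text.
#' @return the PDB text, invisibly when writing to a file.
#' @export
writeStructure <- function(x, file = NULL) {
  a <- atoms(x)
  name4 <- ifelse(nchar(a$elety) >= 4L, substr(a$elety, 1, 4),
    sprintf(" %-3s", a$elety))
  lines <- sprintf(
    "%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
    a$type, a$eleno %% 100000L, name4, a$alt, a$resid, a$chain, a$resno,
    a$insert, a$x, a$y, a$z, a$o, a$b)
  txt <- paste(c(lines, "END"), collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Coerce a structure model into a DomainStructure
#'
#' Convenience for synthetic or pre-trimmed single-domain models.
#'
#' @param model a [StructureModel-class] already renumbered/trimmed.
#' @param ann the domain's [DomainAnnotation-class].
#' @param parent parent label; defaults to the model id.
#' @param chain chain id (default first present).
#' @param domainSlot "N" or "C".
#' @return A [DomainStructure-class].
#' @export
asDomainStructure <- function(model, ann, parent = NULL, chain = NULL,
    domainSlot = "N") {
  a <- model@atoms
  if (is.null(chain)) chain <- a$chain[1L]
  a <- a[a$chain == chain, , drop = FALSE]
  rownames(a) <- NULL
  new("DomainStructure",
    parent = parent %||% (model@metadata$id %||% "unknown"),
    chain = chain, domainSlot = domainSlot, annotation = ann, atoms = a,
    mutations = data.frame(wt = character(), pos = integer(),
      observed = character()))
}
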