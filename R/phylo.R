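#' @include profile-numbering.R
NULL

#' Pairwise p-distance matrix of an alignment
#'
#' The p-distance between two records is the proportion of differing
#' residues over the columns where both are non-gap (pairwise
#' deletion). Intended for numbered-position sub-alignments
#' ([numberedSubalignment()]), from which the family tree is built.
#'
#' @param aln an alignment with at least 2 records.
#' @return symmetric numeric matrix with zero diagonal and the record
#'   ids as dimnames.
#' @export
pdistanceMatrix <- function(aln) {
  m <- .alnMatrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("at least 2 records are required")
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  gap <- m == "-"
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- !gap[i, ] & !gap[j, ]
    if (!any(comp))
      stop("records ", rownames(m)[i], " and ", rownames(m)[j],
        " share no comparable (mutually non-gap) columns")
    d[i, j] <- d[j, i] <- mean(m[i, comp] != m[j, comp])
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration. Negative branch lengths are
#' clamped to 0; ties in the Q criterion are broken deterministically by
#' label order (first minimal pair scanning i < j).
#'
#' @param d symmetric distance matrix with labelled dimnames (>= 3
#'   labels, zero diagonal).
#' @return an `ape::phylo` unrooted tree.
#' @export
neighborJoining <- function(d) {
  d <- as.matrix(d)
  labels <- rownames(d) %||% colnames(d)
  if (is.null(labels)) stop("distance matrix must carry labels")
  n <- nrow(d)
  if (n < 3L) stop("at least 3 labels are required")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  ## active clusters held as newick fragments over placeholder tips
  frag <- sprintf("t%d", seq_len(n))
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  while (nrow(d) > 3L) {
    nn <- nrow(d)
    r <- rowSums(d)
    Q <- (nn - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    ## first minimal (i, j), i < j, in label order
    best <- c(NA_integer_, NA_integer_); bestQ <- Inf
    for (i in seq_len(nn - 1L)) for (j in (i + 1L):nn)
      if (Q[i, j] < bestQ) { bestQ <- Q[i, j]; best <- c(i, j) }
    i <- best[1L]; j <- best[2L]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (nn - 2))
    lj <- d[i, j] - li
    newFrag <- paste0("(", frag[i], ":", fmt(li), ",", frag[j], ":",
      fmt(lj), ")")
    dNew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(nn), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dNew[keep]),
      c(dNew[keep], 0))
    frag <- c(frag[keep], newFrag)
  }
  ## final 3-cluster star: closed-form branch lengths
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- paste0("(", frag[1], ":", fmt(la), ",", frag[2], ":", fmt(lb),
    ",", frag[3], ":", fmt(lc), ");")
  tr <- ape::read.tree(text = nwk)
  tr$tip.label <- labels[as.integer(sub("^t", "", tr$tip.label))]
  tr
}

#' Display label of a domain, with the C-terminal tag
#'
#' C-terminal SH2 domains of dual-domain proteins carry a "-C" suffix
#' (e.g. "SHP2-C"), following the tree-labelling convention.
#'
#' @param proteinId protein identifier(s).
#' @param slot "N" or "C" (vectorised).
#' @return character vector of labels.
#' @export
domainLabel <- function(proteinId, slot = "N") {
  ifelse(slot == "C", paste0(proteinId, "-C"), proteinId)
}

## Quote newick labels containing whitespace or newick metacharacters.
.newickLabel <- function(x) {
  need <- grepl("[][ \t(),:;']", x)
  x[need] <- paste0("'", gsub("'", "''", x[need]), "'")
  x
}

#' Write a tree in Newick format
#'
#' Branch lengths at 6 decimals; labels containing spaces are quoted.
#' [readNewick()] parses the output back to an identical topology and
#' lengths.
#'
#' @param tree an `ape::phylo`.
#' @param file output path, or NULL to return the string.
#' @param digits decimals for branch lengths (default 6).
#' @return the Newick string (invisibly when writing to a file).
#' @export
writeNewick <- function(tree, file = NULL, digits = 6L) {
  stopifnot(inherits(tree, "phylo"))
  nTip <- length(tree$tip.label)
  root <- nTip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  lab <- .newickLabel(tree$tip.label)
  rec <- function(node) {
    if (node <= nTip) return(lab[node])
    es <- kids[[as.character(node)]]
    paste0("(", paste(vapply(es, function(e) paste0(rec(tree$edge[e, 2L]),
      ":", sprintf(paste0("%.", digits, "f"), tree$edge.length[e])),
      ""), collapse = ","), ")")
  }
  txt <- paste0(rec(root), ";")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read a Newick tree
#'
#' Thin wrapper over `ape::read.tree` that also strips the quoting
#' [writeNewick()] applies to labels containing spaces.
#'
#' @param text Newick string (or use `file`).
#' @param file path to a Newick file.
#' @return an `ape::phylo`.
#' @export
readNewick <- function(text = NULL, file = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else
    ape::read.tree(file)
  unq <- function(x) {
    q <- grepl("^'.*'$", x)
    x[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[q]))
    x
  }
  tr$tip.label <- unq(tr$tip.label)
  tr
}

#' Write a distance matrix as a PHYLIP-style square table
#'
#' @param d labelled symmetric matrix.
#' @param file output path.
#' @export
writeDistanceMatrix <- function(d, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(c(rownames(d)[i], sprintf("%.6f", d[i, ])),
      collapse = "\t"), con)
  invisible(file)
}
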