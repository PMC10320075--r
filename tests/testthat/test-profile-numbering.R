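test_that("column conservation is the modal non-gap frequency", {
  aln <- c(a = "RR", b = "RK", c = "R-", d = "RR")
  expect_equal(columnConservation(aln, 1), 1.0)
  expect_equal(columnConservation(aln, 2), 2 / 3)
  expect_equal(columnConservation(c(a = "-", b = "-"), 1), 0)
  expect_error(columnConservation(aln, 3), "range")
  # brute-force tally oracle on a random 20 x 50 alignment
  set.seed(11)
  m <- matrix(sample(c(LETTERS[1:20], "-"), 20 * 50, replace = TRUE,
    prob = c(rep(0.045, 20), 0.1)), nrow = 20)
  rownames(m) <- paste0("r", 1:20)
  expected <- sapply(1:50, function(j) {
    counts <- integer(0)
    for (i in 1:20) {
      ch <- m[i, j]
      if (ch == "-") next
      counts[ch] <- if (is.na(counts[ch])) 1L else counts[ch] + 1L
    }
    if (!length(counts)) 0 else max(counts) / sum(counts)
  })
  expect_equal(columnConservation(m, 1:50), expected)
  # permutation invariance across records
  perm <- m[sample(1:20), , drop = FALSE]
  expect_equal(columnConservation(perm, 1:50),
    columnConservation(m, 1:50))
})

test_that("anchor selection maximises conservation with tie and gap rules", {
  # 10 records; col conservations 0.4, 0.9, 0.6
  col <- function(x) x
  m <- cbind(c(rep("A", 4), rep("C", 3), "D", "E", "F"),
    c(rep("A", 9), "C"),
    c(rep("A", 6), rep("C", 4)))
  rownames(m) <- paste0("r", 1:10)
  expect_equal(selectAnchorColumn(m, 1:3), 2L)
  # ties break to the leftmost column
  m2 <- cbind(c(rep("A", 8), "C", "D"), c(rep("G", 8), "H", "I"))
  rownames(m2) <- paste0("r", 1:10)
  expect_equal(selectAnchorColumn(m2, 1:2), 1L)
  # gap-majority columns are ineligible even if perfectly conserved...
  m3 <- cbind(c(rep("A", 4), rep("-", 6)), c(rep("C", 6), "D", "E", "F", "G"))
  rownames(m3) <- paste0("r", 1:10)
  expect_equal(selectAnchorColumn(m3, 1:2), 2L)
  # ...unless every column is gap-majority
  m4 <- cbind(c("A", rep("-", 9)), c("C", "D", rep("-", 8)))
  rownames(m4) <- paste0("r", 1:10)
  expect_equal(selectAnchorColumn(m4, 1:2), 1L)
  expect_error(selectAnchorColumn(m, integer(0)), "empty")
})

test_that("segment columns number sequentially around the anchor", {
  frag <- numberSegmentColumns(11:15, 13L, "bB")
  expect_equal(frag$index, 48:52)
  expect_equal(numberSegmentColumns(7L, 7L, "aA")$index, 50L)
  # the bBbC turn takes fixed indices 49/50 whatever the anchor says
  turn <- numberSegmentColumns(21:22, 21L, "bBbC")
  expect_equal(turn$index, c(49L, 50L))
  expect_error(numberSegmentColumns(21:23, 21L, "bBbC"), "exactly 2")
  expect_error(numberSegmentColumns(11:15, 99L, "bB"), "anchor")
})

test_that("propagation is column-based and marks contiguity", {
  fam <- makeSyntheticFamily(nRecords = 12, mutationRate = 0.05, seed = 41)
  pr <- propagate(fam@alignment, fam@segmentation)
  # gaps fall only in loops, so every record covers all numbered columns
  for (ann in pr$annotations)
    expect_equal(nrow(positionMap(ann)), nrow(pr$numbering))
  # segment numbering is a bijection onto a consecutive interval over 50
  for (seg in unique(pr$numbering$segment)) {
    idx <- sort(pr$numbering$index[pr$numbering$segment == seg])
    expect_equal(idx, seq(min(idx), max(idx)))
    expect_true(all(c(49L, 50L) %in% idx) || 50L %in% idx)
  }
  # at most one residue per generic number per record
  for (ann in pr$annotations) {
    pm <- positionMap(ann)
    expect_false(anyDuplicated(paste(pm$segment, pm$index)) > 0)
  }
  # a record gapped at the column numbered x51 lacks x51, keeps x50/x52
  aln <- c(t1 = "AACDEFGA", t2 = "AAC-EFGA")
  seg <- c(NA, NA, "bB", "bB", "bB", "bB", "bB", NA)
  pr2 <- propagate(aln, seg)
  anchorIdx <- pr2$numbering$index[pr2$numbering$column == 4]
  pm2 <- positionMap(pr2$annotations$t2)
  expect_false(anchorIdx %in% pm2$index)
  expect_true(all(setdiff(pr2$numbering$index, anchorIdx) %in% pm2$index))
  expect_false("bB" %in% pr2$annotations$t2@contiguous)
  expect_true("bB" %in% pr2$annotations$t1@contiguous)
  # a segment split into two blocks is inconsistent
  expect_error(propagate(aln, c("bB", NA, "bB", "bB", NA, NA, NA, NA)),
    "block")
})

test_that("new sequences are numbered by alignment transfer", {
  fam <- makeSyntheticFamily(nRecords = 10, mutationRate = 0.08, seed = 5)
  pr <- propagate(fam@alignment, fam@segmentation)
  tmpl <- gsub("-", "", fam@alignment[["syn03"]], fixed = TRUE)
  # idempotence: a record's own ungapped sequence gets its own map
  ann <- numberNewSequence(tmpl, fam@alignment, pr$numbering)
  expect_equal(positionMap(ann)[, c("segment", "index", "residue")],
    positionMap(pr$annotations$syn03)[, c("segment", "index", "residue")])
  # 5 seeded substitutions leave the number-to-offset map unchanged
  set.seed(99)
  mutseq <- strsplit(tmpl, "")[[1]]
  at <- sample(seq_along(mutseq), 5)
  mutseq[at] <- vapply(mutseq[at], function(a)
    sample(setdiff(c("A","R","N","D","C","Q","E","G","H","I","L","K",
      "M","F","P","S","T","W","Y","V"), a), 1), "")
  ann2 <- numberNewSequence(paste(mutseq, collapse = ""),
    fam@alignment, pr$numbering)
  expect_equal(positionMap(ann2), positionMap(ann))
  # an oncogenic-style point substitution keeps its generic address:
  # His observed at the template's bDx50 residue still maps to bDx50
  r50 <- resolvePosition(ann, "bDx50")
  mutseq2 <- strsplit(tmpl, "")[[1]]
  mutseq2[r50] <- "H"
  ann3 <- numberNewSequence(paste(mutseq2, collapse = ""),
    fam@alignment, pr$numbering, offset = 580)
  expect_equal(resolvePosition(ann3, "bDx50"), r50 + 579L)
  # dissimilar sequences are refused with the best identity named
  set.seed(7)
  junk <- randomProteinSeq(90)
  expect_error(numberNewSequence(junk, fam@alignment, pr$numbering),
    "identity")
  expect_error(numberNewSequence("ACDEF", fam@alignment, pr$numbering),
    "length")
})

test_that("numbered sub-alignments keep exactly the numbered columns", {
  fam <- makeSyntheticFamily(nRecords = 6, mutationRate = 0.1, seed = 13)
  pr <- propagate(fam@alignment, fam@segmentation)
  sub <- numberedSubalignment(fam@alignment, pr$numbering)
  expect_length(sub, length(fam@alignment))
  expect_equal(unique(nchar(sub)), nrow(pr$numbering))
  expect_error(numberedSubalignment(fam@alignment,
    pr$numbering[0, ]), "empty")
})
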