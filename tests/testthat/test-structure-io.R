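minimalPdb <- paste(
  "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
  "ATOM      3  C   ALA A   1      12.671   7.181  -4.944  1.00  0.00           C",
  sep = "\n")

test_that("PDB parsing keeps coordinates and applies the altloc rule", {
  m <- readStructure(minimalPdb)
  expect_equal(nrow(atoms(m)), 3L)
  expect_equal(atoms(m)$x, c(11.104, 11.639, 12.671))
  expect_equal(atoms(m)$elety, c("N", "CA", "C"))
  # highest-occupancy altloc wins; ties prefer "A"
  alt <- paste(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.40  0.00",
    "ATOM      3  CA BALA A   1       2.000   0.000   0.000  0.60  0.00",
    "ATOM      4  C  AALA A   1       3.000   0.000   0.000  0.50  0.00",
    "ATOM      5  C  BALA A   1       4.000   0.000   0.000  0.50  0.00",
    sep = "\n")
  ma <- readStructure(alt)
  a <- atoms(ma)
  expect_equal(nrow(a), 3L)
  expect_equal(a$x[a$elety == "CA"], 2.0)     # occupancy 0.6
  expect_equal(a$o[a$elety == "CA"], 0.6)
  expect_equal(a$x[a$elety == "C"], 3.0)      # tie -> alt "A"
  # insertion-coded residues stay distinct
  ins <- paste(
    "ATOM      1  CA  ALA A  10       1.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  GLY A  10A      2.000   0.000   0.000  1.00  0.00",
    sep = "\n")
  expect_equal(nrow(atoms(readStructure(ins))), 2L)
  # errors: no ATOM records; malformed line is named by number
  expect_error(readStructure("HEADER    TEST"), "no ATOM")
  bad <- paste(minimalPdb, "ATOM      4  O   ALA A   1     bad", sep = "\n")
  expect_error(readStructure(bad), "line 4")
})

test_that("chain sequences translate 3-letter codes incl. modified residues", {
  txt <- paste(
    "ATOM      1  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  GLY A   2       2.000   0.000   0.000  1.00  0.00",
    "ATOM      3  CA  ARG A   3       3.000   0.000   0.000  1.00  0.00",
    "HETATM    4  CA  MSE A   4       4.000   0.000   0.000  1.00  0.00",
    sep = "\n")
  m <- readStructure(txt, keepHetero = TRUE)
  cs <- chainSequence(m, "A")
  expect_equal(cs$sequence, "AGRM")
  expect_length(cs$resno, nchar(cs$sequence))
  expect_equal(chainSequence(m, "A", mapModified = FALSE)$sequence, "AGRX")
  expect_error(chainSequence(m, "B"), "chain")
})

test_that("renumbering maps author numbers onto the wild-type window", {
  set.seed(3)
  wt <- randomProteinSeq(100)
  model <- makeChainModel(wt, resnoStart = 1L)
  # wild-type window starts at 580: author residue 39 becomes 618
  rn <- renumberToWildtype(model, "A", wt, wtOffset = 580)
  a <- atoms(rn$model)
  expect_equal(sort(unique(a$resno)), 580:679)
  expect_equal(nrow(rn$mutations), 0L)
  old <- atoms(model)
  expect_equal(unique(a$resno[old$resno == 39]), 618L)
  # renumbering preserves residue order
  expect_false(is.unsorted(unique(a$resno)))
  # a His observed where the wild type has Asn is recorded as N642H
  wtN <- wt
  substr(wtN, 63, 63) <- "N"           # wt position 63 -> residue 642
  obs <- wtN
  substr(obs, 63, 63) <- "H"
  rn2 <- renumberToWildtype(makeChainModel(obs), "A", wtN, wtOffset = 580)
  expect_equal(rn2$mutations,
    data.frame(wt = "N", pos = 642L, observed = "H"))
  # unrelated sequences are refused, naming the identity
  expect_error(renumberToWildtype(makeChainModel(randomProteinSeq(100)),
    "A", wt, wtOffset = 580), "identity")
  # residues aligned to no wild-type position are trimmed
  rn3 <- renumberToWildtype(makeChainModel(paste0("GGGGG", wt)), "A",
    wt, wtOffset = 580)
  expect_equal(nrow(rn3$removed), 5L)
  expect_equal(sort(unique(atoms(rn3$model)$resno)), 580:679)
})

test_that("domain extraction splits chains and spans disjointly", {
  set.seed(8)
  seqA <- randomProteinSeq(220)
  model <- makeChainModel(seqA, resnoStart = 1L, id = "entry1")
  # one chain carrying two SH2 spans gives two tagged domains
  bounds <- data.frame(chain = "A", slot = c("N", "C"),
    start = c(10L, 120L), end = c(105L, 215L))
  doms <- extractDomains(model, bounds)
  expect_length(doms, 2L)
  expect_equal(vapply(doms, function(d) d@domainSlot, ""), c("N", "C"))
  r1 <- unique(atoms(doms[[1]])$resno)
  r2 <- unique(atoms(doms[[2]])$resno)
  expect_equal(range(r1), c(10L, 105L))
  expect_length(intersect(r1, r2), 0L)
  expect_true(nrow(atoms(doms[[1]])) + nrow(atoms(doms[[2]])) <=
    nrow(atoms(model)))
  # same domain present in two chains gives one structure per chain
  two <- model
  b <- atoms(model); b$chain <- "B"
  two@atoms <- rbind(atoms(model), b)
  doms2 <- extractDomains(two, data.frame(chain = c("A", "B"),
    slot = "N", start = 10L, end = 105L))
  expect_length(doms2, 2L)
  expect_equal(vapply(doms2, function(d) d@chain, ""), c("A", "B"))
  expect_error(extractDomains(model, data.frame(chain = "C", slot = "N",
    start = 1L, end = 50L)), "empty selection")
})

test_that("write/read round-trips atoms, numbering and coordinates", {
  set.seed(21)
  model <- makeChainModel(randomProteinSeq(50), resnoStart = 601L,
    id = "rt")
  ds <- extractDomains(model, data.frame(chain = "A", slot = "N",
    start = 601L, end = 650L))[[1]]
  txt <- writeStructure(ds)
  back <- readStructure(txt)
  a0 <- atoms(ds); a1 <- atoms(back)
  expect_equal(nrow(a1), nrow(a0))
  expect_equal(a1$elety, a0$elety)
  expect_equal(a1$resno, a0$resno)
  expect_equal(a1$chain, a0$chain)
  expect_equal(a1$resid, a0$resid)
  expect_equal(a1$x, round(a0$x, 3))
  expect_equal(a1$y, round(a0$y, 3))
  expect_equal(a1$z, round(a0$z, 3))
  # a second round trip is bit-stable
  expect_identical(writeStructure(back), txt)
})
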