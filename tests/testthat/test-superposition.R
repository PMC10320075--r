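# All structures here come from the idealized-geometry generator with a
# shared annotation, so the generator's recorded transform is the ground
# truth for every overlay.
famAnn <- makeSyntheticFamily(nRecords = 4, mutationRate = 0,
  seed = 2)@annotations[[1]]

domainWithTransform <- function(R = diag(3), t = c(0, 0, 0), seed = 10,
    parent = "dom") {
  asDomainStructure(makeSyntheticDomainStructure(famAnn, rotation = R,
    translation = t, seed = seed), famAnn, parent = parent)
}

test_that("kabsch recovers exact rigid transforms", {
  ref <- domainWithTransform(seed = 10)
  pr0 <- coreSheetPairs(ref, ref)
  k0 <- kabsch(pr0$P, pr0$Q)
  expect_lt(k0@rmsd, 1e-12)
  expect_equal(k0@rotation, diag(3), tolerance = 1e-9)
  set.seed(101)
  for (rep in 1:5) {
    R <- randomRotation(); tv <- rnorm(3, sd = 8)
    mob <- domainWithTransform(R, tv, seed = 10)
    pr <- coreSheetPairs(mob, ref)
    k <- kabsch(pr$P, pr$Q, pr$positions)
    expect_lte(k@rmsd, 1e-9)
    expect_equal(det(k@rotation), 1, tolerance = 1e-9)
    # the fit undoes the generator's transform
    expect_equal(k@rotation %*% R, diag(3), tolerance = 1e-8)
    expect_equal(as.numeric(k@rotation %*% tv + k@translation),
      c(0, 0, 0), tolerance = 1e-7)
  }
  expect_error(kabsch(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
    "3 paired points")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch(line, line), "degenerate")
})

test_that("kabsch agrees with an independent quaternion oracle", {
  set.seed(202)
  for (rep in 1:100) {
    P <- matrix(rnorm(12, sd = 4), 4)
    Q <- matrix(rnorm(12, sd = 4), 4)
    k <- kabsch(P, Q)
    expect_equal(k@rmsd, quaternionRmsd(P, Q), tolerance = 1e-8)
    expect_equal(det(k@rotation), 1, tolerance = 1e-9)
    # symmetry of the residual
    expect_equal(kabsch(Q, P)@rmsd, k@rmsd, tolerance = 1e-9)
    # invariance under a common rigid transform of both point sets
    R <- randomRotation(); tv <- rnorm(3)
    Pr <- sweep(P %*% t(R), 2, -tv); Qr <- sweep(Q %*% t(R), 2, -tv)
    expect_equal(kabsch(Pr, Qr)@rmsd, k@rmsd, tolerance = 1e-9)
  }
})

test_that("core-sheet pairing intersects positions and backbone atoms", {
  ref <- domainWithTransform(seed = 10)
  pr <- coreSheetPairs(ref, ref)
  pmCore <- positionMap(famAnn)
  nCore <- sum(pmCore$segment %in% c("bB", "bC", "bD"))
  expect_length(pr$positions, nCore)
  expect_equal(pr$nAtoms, 3L * nCore)
  expect_false(any(c("aA", "aB", "bBbC") %in% segmentOf(pr$positions)))
  # a position missing from the mobile drops out of the pairing
  mob <- domainWithTransform(seed = 10)
  drop <- resolvePosition(famAnn, "bCx51")
  mob@atoms <- mob@atoms[mob@atoms$resno != drop, ]
  pr2 <- coreSheetPairs(mob, ref)
  expect_length(pr2$positions, nCore - 1L)
  expect_equal(pr2$nAtoms, 3L * (nCore - 1L))
  expect_equal(dim(pr2$P), dim(pr2$Q))
  # fewer than 9 paired atoms is an insufficient anchor
  tiny <- DomainAnnotation("tiny", layout = "common",
    anchors = data.frame(segment = "bB", index = 50, residue = 10),
    spans = data.frame(segment = "bB", indexMin = 50, indexMax = 51))
  dTiny <- asDomainStructure(makeSyntheticDomainStructure(tiny), tiny)
  expect_error(coreSheetPairs(dTiny, dTiny), "insufficient anchor")
})

test_that("batch superposition recovers transforms and tolerates failures", {
  ref <- domainWithTransform(seed = 10, parent = "ref")
  set.seed(33)
  Rs <- replicate(3, randomRotation(), simplify = FALSE)
  ts <- replicate(3, rnorm(3, sd = 6), simplify = FALSE)
  mobiles <- lapply(1:3, function(k) domainWithTransform(Rs[[k]],
    ts[[k]], seed = 10, parent = paste0("mob", k)))
  out <- superposeAll(c(mobiles, list(ref)), ref)
  expect_length(out, 4L)
  expect_equal(vapply(out, function(o) o$domain@parent, ""),
    c("mob1", "mob2", "mob3", "ref"))
  for (k in 1:3) {
    expect_null(out[[k]]$error)
    expect_lte(out[[k]]$result@rmsd, 1e-9)
    # transformed coordinates coincide with the reference frame
    expect_equal(atoms(out[[k]]$domain)$x, atoms(ref)$x,
      tolerance = 1e-7)
  }
  expect_lte(out[[4]]$result@rmsd, 1e-12)
  # recomputing the rmsd from the transformed coordinates agrees
  prT <- coreSheetPairs(out[[1]]$domain, ref)
  direct <- sqrt(sum((prT$P - prT$Q)^2) / nrow(prT$P))
  expect_equal(direct, out[[1]]$result@rmsd, tolerance = 1e-7)
  # a domain without core annotation fails alone, not the batch
  bare <- out[[1]]$domain
  bare@annotation <- DomainAnnotation("bare", positionMap = data.frame(
    segment = character(), index = integer(), residue = integer()),
    check = FALSE)
  out2 <- superposeAll(list(bare, mobiles[[1]]), ref)
  expect_false(is.null(out2[[1]]$error))
  expect_null(out2[[2]]$error)
})

test_that("session scripts load structures and select highlights as sticks", {
  ba <- bundledAnchors()
  d1 <- domainWithTransform(seed = 10, parent = "domA")
  d2 <- domainWithTransform(seed = 11, parent = "domB")
  txt <- exportSessionScript(list(d1, d2), sheinermanSet())
  lines <- strsplit(txt, "\n")[[1]]
  expect_length(grep("^load ", lines), 2L)
  expect_length(grep("^select gn_", lines), 8L)
  expect_length(grep("^show sticks, gn_", lines), 8L)
  expect_true(any(grepl("gn_bBx50", lines)))
  # deterministic output
  expect_identical(exportSessionScript(list(d1, d2), sheinermanSet()),
    txt)
  # empty highlight: loads only
  only <- strsplit(exportSessionScript(list(d1, d2),
    GenericNumber(character(), integer())), "\n")[[1]]
  expect_length(only, 2L)
  expect_true(all(startsWith(only, "load ")))
  # a position resolvable nowhere becomes a warning comment
  w <- exportSessionScript(list(d1), GenericNumber("aB'", 99))
  expect_match(w, "# warning")
})
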