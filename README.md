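# SH2generic

Generic residue numbering and structural comparison for SH2 domains.

SH2 (Src-homology 2) domains are ~100-residue phosphotyrosine-recognition
modules found in 120 copies across 110 human proteins. Their fold — a
central antiparallel β-sheet sandwiched between two α-helices (the αβββα
motif) — is highly conserved, but residue numbering differs between every
protein, which makes cross-family comparison of equivalent positions
(say, the invariant phosphotyrosine-anchoring arginine of the FLVR motif)
tedious and error-prone. `SH2generic` implements a generic residue
numbering scheme for the family, in the spirit of Ballesteros–Weinstein
numbers for GPCRs:

- each conserved secondary-structure segment (strands bA, bB, bC, bD, bE,
  bF; helices aA, aB′, aB; the bBbC turn) is numbered independently;
- the most conserved alignment column of a segment is its **x50 anchor**,
  and neighbours are numbered sequentially (`bBx49`, `bBx50`, `bBx51`, …),
  so a generic position such as `bBx50` names the same structural
  position in every SH2 domain;
- the two-column bBbC turn carries the fixed indices x49/x50, and loops
  stay unnumbered (their conformations are too variable to compare);
- STAT-family domains use a variant layout that lacks the bE/bF strands
  and carries the aB′ helix instead.

For a protein domain, resolution is plain arithmetic: if `bBx50` is
residue 618 of STAT5B, then `bBx52` is residue 620. The package bundles
the STAT5B reference map (all eight Sheinerman phosphotyrosine-pocket
positions) and the partial SHP2 N-domain map (Y62 at `bEx48`), plus the
FLVR-motif exception list (RIN2, TYK2, SH2D5).

Around the scheme, the package provides the full comparison pipeline:

| module | what it does |
|---|---|
| scheme | parse/format generic numbers, resolve/assign positions, validate annotations (FLVR check) |
| profile numbering | conservation scoring, anchor selection, column numbering, propagation to records and new sequences |
| structure I/O | PDB parsing, renumbering to wild-type, domain trimming/splitting, PDB writing |
| superposition | core-β-sheet (bB/bC/bD backbone) least-squares rigid-body overlays, PyMOL-style session scripts |
| phylogeny | p-distance matrices and neighbor-joining trees over numbered-position sub-alignments, Newick I/O |
| fixtures | synthetic SH2-like families and idealized structures with known ground truth |
| CLI | `exec/sh2generic` with subcommands number, resolve, prepare, superpose, tree, session, fixtures |

## Worked example

```r
library(SH2generic)

## resolve generic positions against the bundled STAT5B map
ba <- bundledAnchors()
resolvePosition(ba$stat5b, c("bBx50", "bDx50", "bDx52"))
#> [1] 618 642 644

assignPosition(ba$stat5b, 642)      # the inverse mapping
#> GenericNumber of length 1
#>   bDx50

sheinermanSet()                     # the 8 pY-pocket positions
#> GenericNumber of length 8
#>   aAx43 aAx47 bBx50 bBx52 bBbCx49 bBbCx50 bDx50 bDx52

## derive numbering for a family from an alignment + segmentation
fam <- makeSyntheticFamily(nRecords = 20, mutationRate = 0.1, seed = 42)
num <- propagate(fam@alignment, fam@segmentation)
head(num$numbering)
#>   column segment index
#> 1      4      bA    48
#> 2      5      bA    49
#> 3      6      bA    50
#> 4      7      bA    51
#> 5      8      bA    52
#> 6     12      aA    43
num$annotations$syn01
#> DomainAnnotation for syn01 (N-terminal domain, common layout)
#>   53 numbered positions in segments: bA aA bB bBbC bC bD bE bF aB

## family tree from the numbered-position sub-alignment
sub  <- numberedSubalignment(fam@alignment, num$numbering)
tree <- neighborJoining(pdistanceMatrix(sub))
substr(writeNewick(tree), 1, 60)
#> [1] "((syn01:0.081536,syn19:0.050539):0.004404,(((syn05:0.097035,"
```

The resolved numbers are the cross-family addresses: 618 is the
anchoring arginine of the STAT5B pY pocket, and 642 (`bDx50`) is the
asparagine whose oncogenic N642H substitution keeps the same generic
address in the mutant — which is exactly what lets mutations be compared
across proteins.

The command-line front end exposes the same operations, e.g.

```sh
sh2generic resolve --protein STAT5B bDx50   # prints 642
sh2generic tree --alignment numbered.fasta --out family.nwk
```

## Scheme resource schema

The scheme ships as `inst/extdata/sh2_scheme.json`:

- `segments_common`, `segments_stat`: parallel arrays `name`, `kind`
  (helix/strand/turn), `rank` (layout order);
- `sheinerman_positions`: the eight pY-pocket generic numbers;
- `flvr_exception_proteins`: proteins whose bBx50 arginine is replaced
  by an aromatic residue;
- `anchor_index`: 50;
- `version`.

Bundled reference annotations live in
`inst/extdata/bundled_anchors.json` (per protein: `anchors` with
segment/index/residue triples and `spans` with inclusive generic-index
ranges).
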