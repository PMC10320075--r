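---
title: "Generic residue numbering for SH2 domains: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generic residue numbering for SH2 domains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SH2generic)
```

## The numbering model

SH2 domains share the αβββα fold: a central antiparallel β-sheet
(strands bB, bC, bD) flanked by helices aA and aB, with peripheral
strands bA, bE, bF; STAT-family domains replace bE/bF with the aB′
helix. Within each conserved secondary-structure segment, residue
positions are structurally equivalent across the family even though
sequence numbering is not. The scheme therefore addresses positions as
`<segment>x<index>`:

- the most conserved alignment column of a segment is its anchor,
  index 50;
- columns left and right of the anchor are numbered sequentially
  (anchor − k ↦ 50 − k), so within a segment, generic index and residue
  number increment together;
- the two-column bBbC turn holds two phosphotyrosine-pocket positions
  and receives the fixed indices x49/x50 — it is too short for a
  meaningful conservation anchor, and its membership in the pocket
  residue set, not the anchor rule, is what earns it numbers;
- loops are deliberately unnumbered: their conformational variability
  means "the same" loop residue does not occupy the same 3D space
  across proteins, so structure-based comparison there is not
  meaningful. Loop residues are addressed informally by flanking-segment
  names (e.g. the bDbE "blocking loop" of SHP2).

Resolution for a given protein is then arithmetic over an anchor: with
`bBx50` = Arg618 in STAT5B, `bBx52` = 620. The inverse map
(`assignPosition`) returns the generic number of a residue, or nothing
for loop/terminal residues.

### Grammar

Labels follow `<segment>x<index>`. Two input aliases are accepted and
normalised: `.` for `x` (the `bE.48` spelling occurs in the field) and
`aBp` (or the Unicode prime) for aB′. Output always uses `x` and the
ASCII apostrophe. Parsing then formatting is the identity over the whole
grammar; the test suite checks this property over every segment and
indices 40–60.

### Bundled reference data

The STAT5B map is bundled with segment spans derived from the printed
legacy indices by the scheme's own arithmetic: bB spans x46–x52 (legacy
βB1–βB7), bD x47–x52 (βD1–βD6), the bBbC turn x49–x50, and aA x42–x50
(αA1 = x42; the span is extended to include the x50 anchor that the
scheme implies for every segment). The SHP2 N-domain entry records the
one printed fact — Y62 at `bEx48`, i.e. a bE strand that begins at x48,
two positions before its anchor — plus the unnumbered bDbE blocking
loop in its free-text notes. Per-segment index spans are data, part of
the scheme resource, not hard-coded: anchors sit off-centre in real
segments and user-supplied alignments define their own spans.

## Deriving numbering from an alignment

Column **conservation** is the modal non-gap residue frequency among
non-gap entries (0 for an all-gap column). This is the simplest
auditable criterion consistent with picking "the most conserved
position", and it is what the anchor selector maximises. Ties break to
the leftmost column; columns that are majority-gap (fraction > 0.5) are
ineligible unless every column of the segment is.

**Propagation is column-based**: every non-gap residue in a numbered
column inherits that column's generic number, and a record gapped at a
numbered column simply lacks that number. We do not re-anchor per
record; the alignment column is the unit of equivalence. Segments with
no internal gaps for a record are marked contiguous in its annotation,
which is what licenses arithmetic resolution later.

**New sequences** are numbered by transfer: the query is globally
aligned (BLOSUM62, gap open 11, extend 1, free end gaps — all
configurable) to the most similar alignment record and column numbers
are carried through the pairwise alignment. Identity is measured as
exact matches over the shorter sequence length, not over the aligned
overlap alone — a short, locally perfect overlap between unrelated
sequences must not pass the floor (default 0.25; the renumbering floor
for structures is 0.9, where near-identity is expected). Segmentation
itself is an input (curated, or from structural annotation); secondary
structure prediction is out of scope.

## Structure preprocessing

PDB parsing keeps fixed-column semantics with explicit policies: for
alternate locations the highest-occupancy conformer is kept (ties
prefer alt-loc A); insertion-coded residues remain distinct through
parsing and are eliminated by renumbering; waters are always dropped
and other heteroatoms dropped by default. Renumbering aligns the
observed chain sequence to the wild-type window and replaces author
numbers by `wt position + offset − 1`; aligned positions with differing
residues become mutation records (e.g. N642H as `(N, 642, H)`), and
structure residues aligned to nothing are trimmed and reported. Domain
boundaries for splitting multi-domain or multi-chain entries are
explicit inputs; automatic SH2 detection is out of scope. Only the PDB
fixed-column dialect is supported in this version (mmCIF is not).

## Superposition

Overlays use the backbone atoms N, CA, C of residues at the generic
positions of the core β-sheet (bB, bC, bD) shared by mobile and
reference — the pairing is by generic number, never by sequence
alignment of atoms. The carbonyl O is excluded: it is the backbone atom
most often missing or variably placed at strand edges, and three atoms
per residue anchor the fit fully. The transform is plain least-squares
(Kabsch, SVD with reflection correction, proper rotation enforced to
det = +1 within 1e−9); there are no outlier-rejection cycles, keeping
the result deterministic. Degenerate (collinear or < 3-point) inputs
are refused. Fewer than 9 paired atoms (3 residues) is treated as an
insufficient anchor. The reference structure is configurable; any
annotated domain can serve, and the synthetic idealized domain is the
bundled default for tests.

Session scripts are plain-text PyMOL-dialect commands: one `load` per
structure, one named selection per highlighted generic position
(`gn_<label>`), shown as sticks. Positions resolvable in no loaded
domain become warning comments, keeping the script line count
deterministic.

## Phylogeny

Family trees are built from the numbered-position sub-alignment, i.e.
exactly the columns with generic numbers, where positional homology is
the scheme's own claim. Distances are p-distances with pairwise
deletion (no substitution model is assumed); a record pair with zero
mutually non-gap columns is an error, not a silent zero. Trees come
from an in-package neighbor-joining implementation with deterministic
tie-breaking (first minimal Q pair in label order) and negative branch
lengths clamped to zero; on additive matrices it reproduces path
lengths exactly (tested at 1e−9, with `ape::nj` as an independent
cross-check). C-terminal domains of dual-SH2 proteins take a `-C` label
suffix. Newick output prints branch lengths at 6 decimals and quotes
labels containing spaces; bootstrap values and likelihood methods are
out of scope, so a published family tree is a qualitative, not exact,
comparison target.

## The synthetic-data generator

`makeSyntheticFamily` emulates the one property the numbering derivation
depends on: segments whose anchor column is strictly the most conserved,
embedded among variable columns and unnumbered loops. The template uses
the common layout with segment lengths chosen so that every bundled
reference index exists (aA x43–x52, bB x46–x52 with its anchor at the
fifth position like βB5, bD x47–x52 with the anchor at βD4's position,
bE beginning at x48 as in the SHP2 N-domain). Defaults are 20 records
at substitution rate 0.1. Non-anchor columns mutate independently at
that rate, with one safeguard: if the i.i.d. draw happens to leave a
non-anchor numbered column untouched in every record, a seed-determined
record is substituted there. Without this, a fully conserved non-anchor
column arises by chance with probability ~0.12 per column at the
default settings, and a left-of-anchor tie would defeat the leftmost
tie-break; the safeguard makes the planted anchor the unique invariant
column of its segment, which is the contract the fixture exists to
provide. The generator is a pure function of its arguments including
the seed, and it restores the caller's RNG state.

Gaps are planted only in loop columns (honouring the rationale for not
numbering loops), and only when the mutation rate is positive, so a
zero-rate family is exactly the template replicated. What the generator
does **not** emulate: realistic substitution processes (no
rate matrices, no site heterogeneity), indels inside secondary
structure, alignment error, or low-complexity bias. Green tests on
these fixtures therefore demonstrate the machinery's correctness — not
that anchor recovery would be unambiguous on hard real families, where
curation ("local structure-based alignments, adjusted iteratively")
remains a manual loop for which the module only provides the
primitives.

`makeSyntheticDomainStructure` emits idealized N/CA/C backbones on
per-segment frames (strand rise 3.4 Å, helical rise 1.5 Å, directions
fanned out so no two segments are parallel and the point set is never
degenerate) with seeded jitter ≤ 0.05 Å. The rigid transform argument
is applied after jitter and recorded in the metadata, so
`kabsch` recovery against the generator's ground truth is exact to
numerical precision.

## Numerical choices and problem sizes

- Anchor ties → leftmost column; NJ Q-ties → first pair in label order;
  altloc ties → conformer A. All ties are deterministic.
- Rotation validity is enforced at det R = +1 within 1e−9; additive-NJ
  and transform-recovery tests assert at 1e−9; the quaternion oracle
  comparison at 1e−8 (two different linear-algebra routes).
- PDB coordinates round-trip at the format's 3-decimal precision.
- The test suite runs families of 6–20 records (~80 columns), batches
  of 3–4 structures (~150 atoms), 100 random 4-point Kabsch instances,
  and trees of up to 12 taxa — sizes at which every oracle is exact and
  the full suite completes in well under a minute.

## Known limitations

- Legacy per-protein labels (αA2, βB5) are stored only as derivation
  commentary, never inferred.
- The bundled scheme covers the printed STAT5B/SHP2 facts; numbering
  any other protein requires a user-supplied alignment or annotation.
- No mmCIF, no structure prediction or retrieval, no docking or
  affinity modelling, no web service; the single-structure pipeline is
  offline by design.
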