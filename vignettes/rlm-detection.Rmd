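---
title: "Detecting and analysing minimal Rossmann-like motifs"
author: "rlmscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and analysing minimal Rossmann-like motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlmscan)
```

## The motif and the model behind the matcher

Rossmann-like domains are doubly-wound three-layer α/β/α sandwiches. The
smallest structural consensus they share — the minimal Rossmann-like motif
(RLM) — is a five-element unit β1–α1–β2–X–β3 in which

* the three strands form a single parallel sheet with spatial order
  β2–β1–β3 (β1 central), i.e. β2 and β3 each hydrogen-bond to β1 in
  parallel orientation;
* α1 (element II) connects β1 to β2 and packs on one face of the sheet,
  forming the first "wind"; the loop between β1 and α1 is the catalytic
  loop, which in many enzyme families carries active-site residues;
* the crossover element X (element IV) carries the chain to the other face
  of the sheet between β2 and β3 and may be an α-helix, a β-strand, or just
  a loop; the crossover creates the crevice between β1 and β3 where
  substrates and cofactors bind.

`matchRLM()` searches for this unit in the space of a structure's
secondary-structure elements (SSEs) and their pairwise relations, encoded in
an interaction matrix: `P`/`A` for parallel/antiparallel hydrogen-bonded
strand pairs, `C`/`T` for packing contacts that are near-collinear vs.
angled, plus a side sign for helix–sheet contacts. Element II must be the
first helix after β1 with no insertions before β2 (the first wind is
compact), while arbitrary SSE insertions are tolerated between β2 and the
crossover element and between the crossover and β3 — that is where classic
Rossmann domains carry their extra β–α units. All three strands must be at
least three residues long. When one (β1, α1, β2, β3) frame is reachable
through several crossover candidates the match is reported once, preferring
a helical IV over a strand IV over a bare loop, and within one kind the
candidate nearest β3 (the element that actually crosses over).

## Secondary structure and the interaction matrix

SSE assignment is dihedral-based: residues are labelled helix
(φ ∈ [−100°, −30°], ψ ∈ [−80°, −5°]) or strand (φ ∈ [−180°, −45°],
ψ ∈ [45°, 225°] mod 360°), single-residue interruptions are bridged, and
runs shorter than 4 (helix) or 3 (strand) residues are dropped. Dihedrals
are only evaluated across intact peptide bonds (C–N < 2.5 Å), so chain
breaks never join elements. A hook accepts externally computed per-residue
SSE strings for users who prefer DSSP-style assignments.

Strand pairs are hydrogen-bonded when at least two backbone N···O pairs fall
below 3.5 Å; parallel vs. antiparallel follows the sign of the axis dot
product. When N/O atoms are missing (CA-only models) the test falls back to
a CA–CA ladder (two consecutive residue pairs at 4.0–6.0 Å). Packing
contacts use a 6.5 Å minimum heavy-atom distance; crossing angles within 30°
of collinear are `C`, the rest `T`. These three thresholds are exposed as
arguments of `buildInteractionMatrix()`. The side of the sheet a helix packs
on is the sign of its centroid against the least-squares plane through the
strands' CA atoms; during matching the plane is refit from the candidate's
own three strands, so the test is local to each putative sheet and the
overall orientation convention cancels.

```{r scan}
fx <- makeIdealRLM()
scan <- scanStructure(fx$structure)
scan$matrix@codes
matchTable(scan$matches)
```

## What the synthetic structures emulate

`makeIdealRLM()` builds backbone geometry from ideal internal coordinates
(standard bond lengths and angles, NeRF chaining), places the three strands
as a genuinely hydrogen-bonded parallel sheet at 4.8 Å spacing — the
inter-strand registry is grid-searched at build time so the N···O bonds are
real, not asserted — and packs a helix on each face at ~4.5 Å minimum atomic
distance. Connecting loops are smooth interpolating paths whose residues are
pinned at φ = +70°, a region outside both SSE dihedral windows, so loops can
never be absorbed into elements regardless of how they bend. The decoy
generator perturbs exactly one motif clause per family (antiparallel β3,
a two-residue β2, a sheet without the crossover bond, both helices on one
face), so a matcher defect localises to a clause.

These fixtures emulate the geometry the motif definition quantifies — sheet
topology, bonding, facing — but not the messiness of real structures:
irregular strand twist, β-bulges, bent helices, missing atoms, or the
near-miss geometries that make real assignment ambiguous. Passing tests
therefore demonstrate that the matcher implements its definition exactly,
not that the dihedral windows or cutoffs are optimal for every deposited
structure; the thresholds are deliberately configurable for that reason.

## Conservation profiles and binning

`conservationIndex()` scores each alignment column with the negated Shannon
entropy of its amino-acid frequencies (gaps excluded; columns above 50%
gaps unscored) and z-scores across columns. The centred scale is what makes
"inside vs. outside" contrasts meaningful: a motif whose elements are more
constrained than their surroundings shows positive means inside and negative
outside. Sequence weighting and window smoothing are intentionally absent
from the default; the index is the plain unweighted entropy variant.

Element binning treats an element's per-residue values as a
piecewise-constant function on [0, L) and evaluates it at bin centres
(i + 0.5)·L/B — one rule that both partitions long elements (L > B) and
stretches short ones (L < B). Default bin counts, when not supplied, are the
rounded mean element lengths over the analysed matches
(`defaultBinCounts()`). `aggregateBins()` averages across family
representatives with the standard error of the mean (zero for a single
profile, by convention).

The inside/outside comparison uses the two-sample Kolmogorov–Smirnov test
with the asymptotic Kolmogorov p-value; exact small-sample p-values are out
of scope, and at the column counts where the contrast is meaningful
(≥ 100) the asymptotic approximation is adequate. The test suite verifies a
type-I error rate within [0.02, 0.09] at α = 0.05 over 200 null alignments
and ≥ 99% power against the planted contrast (dominant-residue probability
0.9 inside vs. 0.3 outside, 200 columns) — both properties of the
implementation, not of any particular dataset.

```{r conservation}
m <- scan$matches[[1]]
msa <- makeMSA(n_seqs = 40, L = 48, rlm_columns = unlist(m@elements),
               p_in = 0.9, p_out = 0.3, seed = 1)
prof <- conservationIndex(msa)
res <- insideOutsideTest(prof, m)
unlist(res)
```

## Enzyme families, pathways and cofactors

Families (ECOD-style F-groups, with multi-domain combinations as distinct
keys) are classified from their pooled EC numbers into four exhaustive
categories: *null* (no EC), *homogeneous* (one EC), *heterogeneous
substrate* (several ECs sharing the first three fields) and *heterogeneous
reaction* (differing in the first three fields). Dashed ECs such as
`2.4.1.-` count as assignments for categorisation but are removed before
pathway mapping (`filterDashed()`), because an unresolved field cannot be
mapped to a reaction.

Pathway over/under-representation is the ratio of observed (motif-bearing
ECs of a class over all motif-bearing ECs in the major group) to expected
(all ECs of the class over all ECs in the group) frequency, with a
two-sided Fisher exact test on the corresponding 2×2 table. p-values are
reported raw by default, matching the uncorrected per-class significance
convention of the source analysis; apply `p.adjust()` downstream if
multiplicity control is wanted. Printed count ratios use half-up integer
rounding (`percentReport()`). Cofactor summaries collapse hybrid iron-sulfur
cluster variants into the two canonical types ([Fe-O-S], [Ni-Fe-S]) before
counting.

## Ligand contacts and binding-mode pooling

A ligand is in contact when any of its heavy atoms lies within 4.0 Å of a
domain heavy atom (hydrogens are rarely deposited, so the heavy-atom
interpretation is used); every motif region within the cutoff is attributed.
Waters and a configurable blocklist of crystallization additives are
excluded. Compound classification is a total function: taxonomy-table
lookup, a manual override that keeps CTP and its derivatives in the
nucleotide superclass, and a "Generic compounds" fallback for everything
unmapped. Biological significance requires membership in the
substrate/product/cofactor sets of an EC assigned to the structure; unmapped
ligands are conservatively "uncertain".

Binding modes are pooled across homologs by element-anchored Kabsch
superposition: corresponding CA atoms are taken element by element (IV only
when helical in both partners), each element pair trimmed symmetrically
about its centre to the shorter length, and the optimal rigid transform is
the closed-form SVD solution. Correspondences under 9 atoms are refused as
under-determined. This replaces general structure alignment deliberately:
within one homology group the motif elements are the shared frame, the
element anchoring makes the correspondence unambiguous, and the result is
deterministic. A hook accepts externally supplied transforms
(`applySuperposition()`) for users who prefer a full structure aligner.

## Numerical choices and degenerate inputs

* Alternate locations resolve to the highest occupancy conformer; only the
  first NMR model is read; waters are dropped at parse time.
* Residue identity is (chain, author number, insertion code) throughout;
  all coordinates in Å.
* An all-gap alignment, a constant-composition alignment (z-score
  undefined), an empty inside/outside partition, and a zero-length element
  in binning are errors, not silent results.
* Matches are reported in deterministic order (element-I start, then
  element-V start); ties among crossover candidates break toward the
  element nearest β3.
* The pipeline is fail-soft: a malformed structure is logged and skipped,
  and the run reports a non-zero status.

## Problem sizes and limitations

The test-suite simulations use 30-sequence, 200-column alignments (200 null
replicates, 100 power replicates), 2 000-entry EC tables for enrichment
recovery, and exhaustive Fisher verification over all 2×2 tables of total
size ≤ 30 — sizes chosen so the full suite exercises every statistical path
in a few minutes while keeping Monte-Carlo bands tight.

Known limitations: the SSE assigner has no π/3₁₀ helix subtypes and no
β-bulge handling; the matcher does not attempt to recover motifs with
deteriorated strands (relaxing clauses is a configuration decision, not a
default); headline census statistics of the source analysis (tens of
thousands of domains, release-dependent pathway totals) require bulk
database downloads and are out of scope — the package reproduces the rules
and the printed count ratios, and verifies the statistical machinery by
construction.
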