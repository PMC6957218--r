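# rlmscan

Detection and functional analysis of the **minimal Rossmann-like motif
(RLM)** in protein structures.

Rossmann-like domains — doubly-wound three-layer α/β/α sandwiches — are
among the most common enzyme scaffolds, and their homologous relationships
are often undetectable by sequence. The smallest structural unit they share
is a five-element motif:

```
β1 — α1 — β2 — X — β3        (elements I … V)
```

with a parallel β-sheet of spatial order **β2–β1–β3** (β1 central, β2 and β3
each hydrogen-bonded to β1 in parallel orientation), α1 packed on one face
of the sheet, and a **crossover** element X (α-helix, β-strand, or bare
loop) that carries the chain to the opposite face between β2 and β3. The
loop between β1 and α1 is the *catalytic loop*; the crevice between β1 and
β3 created by the crossover is the canonical ligand-binding site.

`rlmscan` implements:

* **Motif search**: dihedral-based secondary-structure assignment, a
  pairwise SSE interaction matrix (parallel/antiparallel hydrogen-bonded
  strand pairs, collinear/angled packing contacts with sheet-side signs),
  and an exhaustive, deterministic matcher for the motif with insertion
  tolerance and all three crossover variants (`scanStructure`, `matchRLM`,
  `assignToDomain`).
* **Conservation analysis**: entropy-based, z-scored per-column
  conservation of an MSA, element-wise partition/stretch binning, and an
  inside-vs-outside-motif Kolmogorov–Smirnov contrast
  (`conservationIndex`, `binProfile`, `insideOutsideTest`).
* **Function statistics**: EC parsing and dashed-EC filtering, family
  reaction-heterogeneity categories, pathway enrichment as
  observed/expected frequency ratios with two-sided Fisher exact tests,
  and inorganic-cofactor summaries (`classifyFGroup`, `enrichmentTest`,
  `cofactorJoin`, `percentReport`).
* **Ligand analysis**: 4 Å heavy-atom ligand contacts with motif-element
  attribution, compound-taxonomy classification with totality rules,
  biological-significance flags, and pooling of binding modes across
  homologs via element-anchored Kabsch superposition (`findContacts`,
  `classifyCompound`, `superposeRLM`, `poolLigands`).
* **Synthetic data**: generators for ideal motif structures with real
  backbone hydrogen bonds, single-clause decoys, alignments with planted
  conservation and annotation tables with planted enrichment, so the whole
  pipeline builds and tests with zero downloads (`makeIdealRLM`,
  `makeDecoy`, `makeMSA`, `makeAnnotationTables`).

## Worked example

```r
library(rlmscan)

fx <- makeIdealRLM()                  # ideal β-α-β-α-β sandwich + ground truth
scan <- scanStructure(fx$structure)   # SSEs -> interaction matrix -> matches
matchTable(scan$matches)
#>      structure domain  variant chain   I    II   III    IV     V catalytic_loop crossover_loop
#> 1 ideal_rlm_s1        helix-IV     A 2-6 10-17 22-25 31-38 43-46            7-9          26-30
```

One match, helix-type crossover: elements I/III/V are the three sheet
strands, II and IV the two face helices, and the two loops are reported
with them. A decoy violating any single clause (e.g. β3 antiparallel to β1)
yields zero matches.

Conservation contrast on an alignment with planted motif conservation:

```r
m <- scan$matches[[1]]
msa <- makeMSA(n_seqs = 40, L = 48, rlm_columns = unlist(m@elements),
               p_in = 0.9, p_out = 0.3, seed = 1)
prof <- conservationIndex(msa)
unlist(insideOutsideTest(prof, m))
#>  mean_in mean_out        D  p.value     n_in    n_out
#>   0.7883  -1.2031   1.0000   0.0000       29       19
```

Motif columns average +0.79 on the z-scored conservation scale against
−1.20 outside, and the KS test separates the two distributions completely
(D = 1) — the planted signal is recovered. Count-ratio reporting uses
half-up integer percentages, e.g. `percentReport(21, 31)` prints `68`: of
31 enzymes in a pathway, 21 motif-bearing ones are 68%.

A thin command-line wrapper is installed with the package
(`system.file("scripts", "rlmscan.R", package = "rlmscan")`) exposing
`scan`, `fixtures` and `run` subcommands; `runPipeline()` is the same entry
point as an R function.

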