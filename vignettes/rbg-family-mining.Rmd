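---
title: "Mining RNA-binding glycine-rich (RBG) gene families: methods and design"
author: "rbgminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining RNA-binding glycine-rich (RBG) gene families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbgminer)
```

## The biological problem

Glycine-rich proteins (GRPs) are a large plant protein family defined by
(Gly)n-X repeats. Class IV of that family — the RNA-binding glycine-rich
proteins, RBGs — couples the glycine-rich region to nucleic-acid-binding
domains and is repeatedly implicated in abiotic-stress responses (cold, heat,
salt, drought, ABA). Within Class IV, four subclasses are distinguished by
domain arrangement:

* **IVa** — one RNA-recognition motif (RRM) plus the glycine-rich C-terminal;
* **IVb** — one RRM plus a CCHC zinc knuckle;
* **IVc** — a cold-shock domain (CSD) with two or more zinc knuckles
  (conventionally *excluded* from the RBG family proper, since CSD proteins
  cluster with the cold-shock superfamily);
* **IVd** — two RRMs.

`rbgminer` implements the complete genome-wide identification workflow for
this family — domain-grammar classification, physicochemical
characterization, pairwise identity/similarity, neighbor-joining phylogeny
with bootstrap, tandem-duplication and syntenic-ortholog detection, and
qPCR 2^-ddCt expression profiling — and pairs every stage with a synthetic
data generator that plants recoverable ground truth. The package is
deliberately self-contained: no external HMM scans, aligners or genome
downloads are needed for any test, although an hmmscan `--domtblout` table
and an externally computed MSA are accepted wherever domain evidence or an
alignment is expected.

## Identification model

### Motif grammar

The RRM is detected through its two diagnostic submotifs, scanned as
degenerate consensus patterns:

* RNP-1 (8 residues): `(K/R) G (F/Y) (G/A) F V x (F/Y)`
* RNP-2 (6 residues): `(L/I) (F/Y) (V/I) (G/K) (G/N) L`

Scanning is non-overlapping and left-to-right. An RRM *call* pairs an RNP-2
with the nearest unused downstream RNP-1 whose inter-motif gap lies in a
configurable window, 10–60 residues by default. The window reflects the
canonical RRM geometry — RNP-2 on strand β1, RNP-1 on β3, roughly 20–35
residues apart inside an ~80-residue domain — with slack on both sides. The
greedy left-to-right pairing equals an exhaustive maximum matching on all
realistic inputs (property-tested against full enumeration).

CCHC zinc knuckles use the canonical `C-x2-C-x4-H-x4-C` pattern (14
residues). The literature names the domain without printing a consensus, so
the pattern choice is ours; it is the standard retroviral-type knuckle
definition. Cold-shock domains have no usable short consensus at all — in
practice they are identified with profile HMMs — so the built-in scanner
never sets the CSD flag; it is populated only from an external domain-hit
table (or known a priori). A consequence worth noting: on scanner-only
evidence an IVc protein is rejected by the "no RRM" rule rather than labelled
`IVc_excluded`; membership is unaffected either way.

`X` residues are treated conservatively: they match only the wildcard
position of RNP-1, never a constrained position, so undefined residues
cannot manufacture false motifs.

### Membership rules

A protein is an RBG family member when it carries at least one RRM and its
C-terminal region is glycine-rich, strictly above 20% — a fraction of
exactly 0.20 fails. The C-terminal region is defined from just after the
last RRM span to the end of the sequence (the whole sequence if no RRM); the
field's literature does not pin down the region, and this post-RRM reading
is one defensible choice, kept configurable. Rule order matters: the IVc
exclusion (CSD + ≥2 CCHC) is evaluated *before* the glycine filter so a
cold-shock decoy can never leak through as IVb.

When domain evidence comes from an external profile-HMM table instead, rows
are filtered by model coverage ≥ 60% and E-value ≤ 1e-5 — both boundaries
inclusive ("at least" / "cutoff of") — and surviving RRM-model hits are
counted per protein.

Members are named `RBGA1..`, `RBGB1..`, `RBGD1..` by subclass in chromosome
order (chromosome name, then start). The numbering convention is the
package's own; published family tables inherit theirs from earlier work
without restating it.

### Physicochemical properties

Molecular weight is the sum of average residue masses plus one water
(`X` contributes the mean residue mass). The isoelectric point solves
net-charge = 0 by bisection on pH 0–14 to 1e-3, with the
Henderson–Hasselbalch sum over both termini and the D/E/C/Y/H/K/R side
chains. The default pKa set is the Bjellqvist/ExPASy-style table (with
residue-specific N-terminal values); the table is swappable because the
upstream tools only cite the ExPASy service, not constants. Undefined
residues are excluded from the charge sum and reported via a message rather
than an error — real family tables occasionally skip a pI for exactly this
reason.

## Alignment and phylogeny

Pairwise identity/similarity matrices use affine-gap global
(Needleman–Wunsch/Gotoh) alignment via `Biostrings::pairwiseAlignment`,
with EMBOSS-needle-style defaults: BLOSUM62, gap opening 10, gap extension
0.5 (a gap of length L costs `10 + 0.5 L`). Identity is matches over the
*full* alignment length including gap columns (the needle convention);
similarity additionally counts positive-scoring mismatches. The test suite
checks the affine scores against an exhaustive dynamic program that
enumerates gap lengths directly, with no three-state decomposition.

For tree building the package provides a deliberately naive center-star
progressive aligner (center = highest summed pairwise identity; pairwise
alignments merged on the center's coordinate frame, insertions left-aligned).
It is not a MUSCLE/MAFFT replacement — no iterative refinement, no guide
tree — but it is deterministic, dependency-free, and adequate for the
conserved-core families the pipeline targets; an externally computed aligned
FASTA can be supplied instead.

Columns with non-gap occupancy below 70% are masked (a column at exactly
0.70 is kept). Distances on the masked MSA are p-distances over mutually
non-gap sites, Poisson-corrected (`-ln(1 - p)`) by default. **JTT
maximum-likelihood distances are not implemented**; the Poisson correction
is a stated stand-in for the JTT model option of MEGA-style workflows, and
the raw p-distance is selectable. When `p >= 1` the Poisson distance is
clamped to a configurable ceiling with a warning.

Neighbor-joining is implemented directly (Saitou–Nei Q-criterion) because
the package pins down two behaviors that off-the-shelf implementations leave
open: ties in Q are broken by the lexicographically smallest label pair, so
the tree is a pure function of the matrix, and negative branch lengths are
clamped to zero with the deficit moved to the sibling edge. `ape::nj` serves
as an independent cross-check in the tests, which also verify exact recovery
of random additive matrices — the defining property of NJ. Bootstrap support
resamples masked columns with replacement, 1000 replicates by default, and
scores each internal edge by the fraction of replicate trees containing its
bipartition (counted with `ape::prop.clades`).

## Tandem duplication and synteny

Two member genes are tandem duplicates when they sit on the same chromosome
separated by at most 10 annotated genes *and* at most 200 kb; both
thresholds are inclusive. Intervening genes are counted over *all* annotated
genes, not family members only (the stricter reading; configurable).
Distance is start-to-start, since the rule's anchor point is conventionally
unstated. An O(n²) all-pairs oracle over every fixture backs the
implementation in the tests.

Syntenic orthologs follow the SynOrths recipe: reciprocal best hits by
affine global alignment score (with a k-mer prescreen for speed and an
exhaustive mode for oracle tests; ties break to the lexicographically
smaller id), confirmed by flanking-gene collinearity — among the 10 genes on
each side of gene *a*, at least 2 must have best hits within 10 ranks of *b*
on *b*'s chromosome. `flank_k = 10`, `min_support = 2` are package defaults;
the published SynOrths parameters are not printed anywhere accessible.
Chromosome ends truncate the flank window without lowering the support
threshold, and `min_support = 0` degenerates to plain reciprocal best hits.
Strand is carried in the annotation but deliberately ignored by both rules.
Each member is finally labelled `tandem`, `syntenic_retained`, or
`dispersed`, in that precedence order.

## Expression profiling

Replicate Ct tables (target and reference gene per well) are reduced by the
Livak 2^-ddCt method. Replicates are averaged on the ΔCt (cycle) scale —
not the fold scale — which is the standard reading of the method; the
reported cell is `log2(2^-ddCt) = -ddCt`, so the calibrator column (leaf
tissue, or the 0 h time point) is identically zero by construction.
Replicate scatter is carried along as the SD of replicate ΔCt. Two exact
invariances are tested: shifting every reference Ct by a constant leaves the
matrix unchanged, and shifting one gene's target Ct in one sample by *c*
moves exactly that cell by *-c*.

Heat-map row ordering uses average-linkage hierarchical clustering on
Euclidean distances (`stats::hclust`); rows are sorted by gene id first so
the ordering is invariant under input permutation, and a 2-group dendrogram
cut mirrors the two-category expression split such family studies report.
No significance machinery is attached: the heat maps are descriptive.

## The synthetic-data generator

The generator is first-class, tested code: every pipeline stage is validated
against what it plants.

* **Proteomes.** Planted architectures per subclass (RNP instances drawn
  uniformly from the printed consensus alternatives; RNP-2 20–35 residues
  upstream of RNP-1; knuckles spliced into the tail; a fixed 65-residue CSD
  placeholder for IVc) plus background proteins. Spacers, linkers and tail
  filler draw from an alphabet that cannot form RNP or CCHC instances, and
  background proteins are rejection-sampled to contain no RNP-1 — clean
  negatives by construction. Emitted members are rescanned and resampled
  until the planted counts are recovered, so truth recoverability is a
  generator guarantee, not a hope. Defaults: 5 IVa + 3 IVb + 3 IVd members,
  2 IVc decoys, 50 background proteins, member tail glycine 0.45, background
  glycine 0.10. A member glycine fraction at or below the 0.20 threshold is
  refused outright (it would make the planted truth unrecoverable by
  design).
* **Genome pairs.** Species A: 3 chromosomes x 65 genes, gene lengths
  0.9–2.4 kb, intergenic gaps 8–20 kb, members placed one per 13-gene
  segment so scattered members can never satisfy the tandem rule; one
  planted 3-gene tandem array at 30 kb start-to-start spacing (arrays that
  violate the tandem definition itself are refused). Species B preserves
  gene order within 20-gene collinear blocks (block order shuffled),
  orthologs are mutated at 5% per residue, 5% of background genes are
  relocated by default, and optional member relocations provide synteny
  negative controls. Tandem-array B copies are resampled until each planted
  ortholog dominates the alignment scores both ways, keeping ortholog truth
  recoverable even among near-identical paralogs.
* **Ct tables.** Per replicate, target Ct = per-gene baseline − planted
  log2 fold-change + N(0, sd); reference Ct constant up to the same noise;
  triplicates; sd defaults to 0.2 cycles. With sd = 0 the pipeline recovers
  the planted effects to machine precision, and the replicate-noise
  propagation (sd of a recovered cell = `noise * sqrt(4/3)` for triplicates)
  is verified by simulation.

What the generator does **not** emulate: indels and codon-level evolution,
paralog families among the background, segmental duplications, unequal
clade rates, amplification-efficiency differences between qPCR wells.
Passing the recovery tests therefore demonstrates correctness of the rules
and algorithms, not robustness to every idiosyncrasy of real genomes —
which is the appropriate claim for an identification pipeline whose real
inputs are curated proteomes and annotations.

## Numerical and design choices

* Coordinates are 1-based closed intervals throughout (`GRanges`/`IRanges`
  convention), with gene ranks 0-based per chromosome; gap and intervening
  counts are adjusted accordingly at each rule.
* One global seed fans out to per-stage child seeds by stable hashing of the
  stage name (`stageSeed`), so stages rerun in isolation reproduce their
  in-pipeline streams; two runs with the same configuration are
  byte-identical, artifact for artifact.
* Determinism over micro-optimization: ties are always broken
  lexicographically (best hits, NJ joins, naming, clustering order).
* Degenerate inputs warn rather than fail where a downstream default exists
  (empty GFF, zero-length C-terminal region, n < 3 taxa, constant
  expression matrix) and fail loudly where silent repair would corrupt
  results (duplicate FASTA ids, negative Ct, end < start, all columns
  masked).
* Default problem sizes (63-protein proteomes, 195-gene genomes, 20-seed
  recovery sweeps, 200-replicate bootstrap demonstrations) are chosen so the
  full validation suite runs on a laptop in a few minutes while still
  exercising every rule boundary; all of them scale up through the
  configuration.

## Known limitations

* Poisson-corrected distances are not JTT ML distances; trees on strongly
  diverged families may differ from MEGA/JTT topologies near weak edges.
* The center-star MSA is a fallback, not a production aligner.
* CSD detection requires external domain evidence by design.
* The synteny detector assumes comparable gene densities between species;
  wildly different annotation granularities would distort the rank-window
  support rule.
* Headline counts from any particular published family table (e.g. member
  totals of a specific crucifer genome) require that genome's proteome and
  annotation as input; the package validates the method on planted truth
  and accepts real genomes as a documented re-run.
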