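---
title: "Methods and design notes for rhepipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for rhepipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhepipe)
```

`rhepipe` implements the downstream half of a root-hair (RH) versus
non-root-hair (NRH) RNA-seq comparison: differential-expression filtering,
degenerate cis-element scanning, co-expression network construction, module
mining and GO enrichment.  This vignette records the models, the defaults
and the design decisions — especially the places where the procedure had
genuinely open choices.

## Differential expression

The filter consumes a Cuffdiff-style per-gene table (RPKM in both
conditions, FDR-adjusted *q*-value, test status) and applies three rules:

1. *q* < 0.05,
2. fold change > 2 in either direction, i.e. |log2 fc| > 1, with infinite
   fold changes passing,
3. RPKM > 1 in at least one condition.

All three comparisons are **strict**, following the wording "less than" /
"greater than" / "more than".  Fold change is `log2(RPKM_NRH / RPKM_RH)`:
RH-enriched genes are negative.  When exactly one abundance is zero the
fold change is ±∞ (reported tables print `inf`); both-zero rows are
undefined and the low-level helper refuses them unless asked to return
`NA` for whole-table derivation.  "Detected only in RH" is interpreted as
NRH RPKM **exactly** zero (consistent with the `inf` convention) guarded by
RH RPKM ≥ 1.

Two details are the package's own conventions because the source material
is ambiguous:

* **Rounding of overlap percentages.**  The published roundings are
  internally inconsistent (1259/1617 = 77.9% appears as "seventy-seven
  percent" while 4150/5409 = 76.7% appears as "77%").  `overlap_stats()`
  rounds to the nearest integer, halves away from zero, and documents it.
* **Status handling.**  Whether the upstream 5409-gene filter also required
  Cuffdiff status `OK` is unstated; `filter_de(require_ok = TRUE)` requires
  it by default (matching the "confidently identified" phrasing) and the
  flag makes the other reading available.

`compute_rpkm()` is the standard `1e9 · C / (L · N)` normalisation;
`flag_novel_loci()` calls a merged locus novel only when its exonic span
overlaps no reference gene span on the same chromosome (strand-agnostic,
any overlap — even 1 bp — disqualifies).  Expression-pattern clustering
uses hierarchical agglomeration with distance 1 − *r* and average linkage,
cut to *k* groups; zero-variance genes are dropped with a warning because
the distance is undefined for them.

## RHE consensus scanning

The Root Hair Element consensus `WHHDTGNNN(N)KCACGWH` carries one optional
base: both the 16-mer and the 17-mer expansion are scanned everywhere.
Matching is per-position set membership of IUPAC codes; an `N` in the
*subject* sequence (an assembly gap) matches only an `N` in the consensus —
a conservative choice so gaps never fabricate hits.

Three region classes are extracted per gene model, all on the coding
strand:

* **promoter** — the 3000 bp immediately 5′ of the start codon (the
  translation start, not the TSS, per the "−3000 bp" convention),
  truncated at the chromosome edge;
* **intron** — each intron separately, indexed in transcription order;
* **CDS** — the spliced concatenation of CDS segments in translation
  order.  A match that straddles an exon–intron boundary in genomic space
  is deliberately *not* a CDS hit; only the spliced text counts.

Hit coordinates are 1-based and local to the region window (the original
table's numbering base is unstated, so window-local is the package's
documented choice).  Reverse-orientation hits — windows whose reverse
complement matches the consensus — are reported with descending
`start > end` and `matched_seq` equal to the region-strand window text.
That readout convention follows the published hit table, whose
descending-coordinate rows print the plus-strand text (e.g.
`AACGTGAACACCATGGA`, which fits the consensus only after reverse
complement).  Two hits are duplicates only if orientation, leftmost
position and length all coincide, so overlapping 16/17-mer hits are both
reported.  Internally the scanner slides precomputed allowed-base sets;
tests pin it to a position-by-position brute-force matcher and to
Biostrings' independent degenerate matcher.

## Co-expression networks

Pearson correlation is computed on the compendium as loaded — the package
assumes upstream normalisation (the study used RMA on its 2671-array
collection before hand-picking 300 root-related arrays) and does not
re-normalise.  Edges connect pairs with r ≥ threshold (default 0.83); a
gene becomes a node only if it keeps at least one edge, which is why a
network can have "122 nodes from 124 genes".  The enrichment-guided sweep
rebuilds the network over a grid (default 0.70–0.90, step 0.01 — the
original series' step is unstated, so the step is configurable) and scores
each threshold by the number of GO terms with p below `sweep_alpha`
(default 10⁻³); "best enrichment" is qualitative in the source, so a
min-p statistic is available behind a flag.  Ties choose the largest
threshold (sparser network).  Bait–prey networks compute all edges among
baits ∪ preys and then delete every prey–prey edge, so each surviving prey
touches a bait.

## Module mining

Vertex weight is the plain clustering coefficient
`Ci = 2n / (Ki(Ki − 1))` (0 when Ki < 2).  The original MCODE publication
scales this weight by the k-core number of the neighbourhood; the procedure
implemented here uses the unscaled coefficient, which is what the study
describes, and the divergence is noted here on purpose.  Seeding picks the
highest-weight unassigned node (ties: lexicographic id); expansion is
breadth-first and a neighbour joins while `W_j / W_seed > 0.1`.  Assigned
nodes are removed from both later seeding and later expansion — a hard
partition, matching "deleting the searched node from the network".
Post-filters keep modules with more than 5 nodes and induced minimum
degree ≥ 2; the original degree threshold is never stated, so 2 (every
member keeps two in-module partners) is the package default and is
configurable.  No depth limit is imposed.

## GO enrichment

`hypergeom_upper(x, M, K, N)` is the exact one-sided over-representation
tail P[X ≥ x] via `phyper`.  Only enrichment is tested (the study reports
no depletion) and no multiple-testing correction is applied to GO p-values
(reported values are raw).  The **elim** walk orders terms by longest-path
depth from the root, deepest first, ties by term id — a deterministic
reading of "higher level GO terms".  Each term is tested on its current
annotation set; if p < `alpha_elim` its genes are removed from all
ancestors before those are tested.  `alpha_elim` defaults to 0.01 (the
topGO default; the study states only reporting cutoffs of 10⁻³ and 0.01),
and `alpha_elim = 0` provably reduces elim to the classic test — a
property the suite checks.  Only `is_a` edges are parsed from OBO input;
other relationship types are ignored with a warning because the elim
procedure needs only the subsumption hierarchy.  Annotations are closed
under the true-path rule at load time.

## The synthetic world

The generators define the study conditions the tests run under:

* **Diff table** — log-normal RPKM baseline (meanlog log 3, sdlog 1.5),
  spanning roughly 0.1–5000 RPKM like the published tables.  Non-DE genes
  get |log2 ratio| < 1 and q ~ U(0.05, 1); DE genes |log2 effects| from
  [1, 4] and q ~ U(0, 0.05); q-values are *drawn*, not computed, because
  the upstream test is out of scope — the filter consumes q-values, it
  does not define them.  DE baselines are redrawn until > 1 so rule 3
  never silently removes planted truth.  A configurable subset of DE genes
  is "RH-only" (NRH = 0).  Consequently `filter_de()` recovers the planted
  truth *exactly*; this is by construction, and what it demonstrates is
  correctness of the rule logic, not statistical power on real data.
* **Compendium** — module members follow `x = s·z + sqrt(1 − s²)·ε` with a
  shared per-array latent z and unit noise, giving expected within-module
  correlation s²; defaults s = 0.95 over 300 arrays put module pairs near
  r ≈ 0.90, safely above the 0.83 cutoff, while the null correlation of
  background genes has sd ≈ 1/sqrt(300) ≈ 0.06, making spurious edges at
  0.83 a ≈ 14σ event.  Planted modules of 20 and 9 genes mirror the
  published two-module outcome.  Module genes occupy the leading id block
  and are forced into the RH-up-regulated DE truth so the pipeline's
  DE → network → modules chain is coherent end to end.
* **Genome** — three-exon gene models on alternating strands, each with a
  3000 bp promoter clearance; consensus instances are drawn uniformly from
  the degenerate sets and planted in promoter, a random intron, and inside
  a single CDS exon (so planted CDS hits are contiguous in both genomic
  and spliced space).  Rejection sampling regenerates a gene block until
  scanning returns exactly the planted truth, so recovery tests are exact
  rather than probabilistic.
* **Ontology** — each non-root term gets 1–2 parents among earlier terms
  (acyclic by construction) and a random direct annotation; one designated
  term's annotation overlaps the study set `fold`-fold above the
  hypergeometric expectation (x = fold·K·M/N study hits), which is
  infeasible when fold·M > N — the generator errors rather than silently
  clipping.

What the synthetic data does **not** emulate: count noise and
length-dependent RPKM variance, correlated q-values, isoform structure,
UTRs, overlapping genes, motif GC-composition bias, and the scale-free
topology of real co-expression networks.  Passing recovery tests therefore
validates algorithmic correctness under known truth, not robustness to
real-data pathologies.

## Numerical and reproducibility choices

Percentages round half away from zero.  All generator randomness flows
from one master seed through fixed per-stage offsets, so stages are
reproducible in isolation; `run_pipeline()` writes MD5s of every artifact
and two runs with one seed are byte-identical.  Determinism extends to
tie-breaks: component ordering (size, then smallest member), module
seeding (weight, then id), elim ordering (depth, then id).  Edge weights
are stored with `from < to` canonically.  Test and acceptance problem
sizes — 5000 genes for the DE recovery, 200 genes × 300 arrays for the
network recovery, N ≤ 60 for the exhaustive hypergeometric sweep, 100
replicates for the elim ranking, 200 × 2 kb for the scanner oracle — were
chosen so each check runs in seconds while leaving no realistic room for
an implementation error to hide.

## Known limitations

Dataset-level published counts (5409 DE genes, 61 RH-only, 121 novel
transcripts, 201 promoter RHE hits, the exact module memberships) depend
on the deposited raw reads and the 300-array compendium and are not
reproducible from printed material; the package validates the *arithmetic
and algorithms* on the printed tables plus planted-truth synthetic data
instead.  The scanner targets short degenerate consensi, not PWMs; the
module miner implements the described clustering-coefficient variant, not
full MCODE with fluff/haircut post-processing; UTR regions are not
scanned.
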