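---
title: "Detecting enhanceosome-like TF dimer arrangements in open chromatin"
author: "enhanceodimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting enhanceosome-like TF dimer arrangements in open chromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhanceodimer)
```

## The problem and the model

The interferon-β enhanceosome is a 57-bp enhancer with an unusually rigid
architecture: NF-κB, ATF-2/c-Jun and IRF activators plus three HMG I(Y)
sites (HMG-A, HMG-B in PRD IV, HMG-C in PRD II) bind at fixed spacings, and
1-bp perturbations abolish activity. The question this package
operationalises: do sub-dimers of that complex — a *motif pair with a fixed
mutual orientation and spacing* — recur as overrepresented arrangements in
cell-type–specific open chromatin, and how does their genome-wide spacing
compare with the enhanceosome's?

The analysis proceeds in five stages, each an exported function family:
motif scanning (`scanSequence`, `balancedThreshold`), dimer discovery
(`discoverDimers`), enhanceosome matching (`matchEnhanceosome`), genomic
context (`annotateNearestGene`, `assignState`, `gplusBinomial`), and
cross-species comparison (`goEnrichment`, `buildPartition`,
`compareGeneSets`).

## Motif scoring and the balanced threshold

A PWM stores counts, a pseudocount fraction and a background composition.
Smoothed column probabilities add `pseudocount * columnTotal` of mass,
distributed across bases proportionally to the background (default 0.01;
the source analyses do not state a smoothing rule, so this is a package
convention). Windows score as sums of per-position log₂ odds; windows
containing N are disqualified (score −∞) rather than averaged; minus-strand
windows are scored through the reverse-complemented matrix.

The scanning cutoff is the *balanced threshold*: with
FPR(t) = P(score ≥ t | background) and FNR(t) = P(score < t | motif),
both computed from **exact** discretised score distributions (column-wise
convolution, bin width 0.1 bits by default — no sampling), the threshold is
the smallest grid point t with FPR(t) ≤ ρ·FNR(t), ρ = 100 by default. FPR
is nonincreasing and FNR nondecreasing in t, so the solution set is an
upper interval and "smallest" is well defined. Two conventions the
definition leaves open were pinned as follows:

* strictness — FPR uses ≥ t, FNR uses < t, which keeps both monotone and
  the ratio well-defined at the extremes;
* the threshold is a grid point of the discretised distributions, not an
  interpolated score. Scanning then compares *exact* window scores against
  that grid value; the discretisation only enters threshold construction.

Discretisation is per column (bin index `round(score/binWidth)`, then
summed), so the exact dynamic program and the 4^w enumeration oracle in
the tests share one definition. A width-1 uniform PWM consequently has a
single score atom of mass 1 — distinct words with equal scores collapse.

Degenerate PWMs where no grid point satisfies the ratio return the maximal
achievable score with a warning.

## Dimer discovery and the enrichment statistic

Open-chromatin peaks arrive as narrowPeak (BED6+4). Per replicate, up to
50,000 peaks with top `signalValue` are kept (ties broken by position, so
selection is stable and idempotent); peaks whose sequence is more than half
masked are excluded outright ("majority" rule, strict); replicates of one
cell type are merged by interval union after selection. Motif hits
overlapping the mask are dropped before pairing.

Spacing is *end-to-start*: the gap in bp between the end of the upstream
hit and the start of the downstream hit; negative values encode overlap
(enhanceosome sites themselves overlap, so overlap must be representable).
Every hit pair inside one peak with |spacing| ≤ 50 bp (default) becomes an
instance of a canonical structure: of an arrangement and its
reverse-complement image — swap the motifs, flip both strands, keep the
spacing — the lexicographically smaller (pwmA, pwmB, strandA, strandB)
tuple is kept, with "+" before "−". Homodimer pairs are unordered and a
hit never pairs with itself.

Per structure and cell type, overrepresentation against the pooled
remaining cell types is tested exactly: with k_t target and k_b background
instances over bp_t and bp_b of open chromatin,

p = P(X ≥ k_t), X ~ Binomial(k_t + k_b, bp_t / (bp_t + bp_b)),

with Benjamini–Hochberg q-values per cell type and a minimum
target-instance count of 1 (no lower bound beyond existence). **This
statistic is the package's own choice**: the external dimer-discovery tool
whose workflow this mirrors does not publish its internal test, so an
exact, dependency-free rate comparison with the same interface is used and
documented as a substitution, not a reproduction. Open questions that the
substitution makes concrete — pooled vs pairwise backgrounds, whether
replicate merging precedes top-peak selection — are pinned to: pooled
background, selection before merging.

## Enhanceosome matching

`builtinSequences()` carries the two printed 57-bp sequences as constants
(human hg19 chr9:21,077,989–21,078,045, 44 bp upstream of *IFNB1*; mouse
mm9 chr4, 101 bp upstream of *Ifnb1*; no mouse coordinates are published,
so the anchor stores NA). Mismatch positions are reported 1-based, matching
prose conventions.

`matchStructure` pairs enhanceosome hits of a structure's two motifs whose
canonical orientation equals the structure's and whose spacing differs by
at most ±2 bp (default). Δ = enhanceosome spacing − structure spacing, so
the headline genome-wide observation — arrangements 1 bp *tighter* than the
enhanceosome — reads Δ = +1. Matches with tolerance t are a superset of
tolerance t−1 matches by construction.

Hits map to named layout sites by maximal base overlap, ties to the
leftmost site; site pairs outside the four named groups are "other". The
default layout transcribes the published architecture, which is reported
only graphically, so the table is configurable. One deliberate adjustment:
the HMG-C site extends 2 bp past the right edge of the NF-κB site, because
a site strictly nested inside another can never win a maximal-overlap
assignment.

## Genomic context conventions

* Instance midpoint = `floor((start+end)/2)` on 0-based half-open
  intervals; even-length intervals take the left-of-center base. The
  midpoint represents the instance in state assignment, gene membership and
  enhancer membership alike (partial-overlap handling is otherwise
  undefined).
* Nearest gene: distance 0 inside a gene body (intronic whenever discovery
  masked exons — the masking guarantees hits avoid exons, and exons in this
  package's worlds are longer than the maximal spacing, so midpoints cannot
  fall in one); otherwise the nearest gene-boundary point, ties to the
  lexicographically smaller gene id.
* Q1–Q6 distance queries use strict `<` at 100/500/1,000/5,000/10,000/
  50,000 bp, as does the ±10 kb TSS window (a midpoint exactly at the
  boundary is outside). Q0 is within-gene selection.
* The G-plus group is {Strong_Enhancer, Active_Promoter, Weak_Promoter,
  Weak_Enhancer}; `gplusBinomial` is the exact binomial upper tail. The
  background probability p0 is not published for the original analysis, so
  the natural estimate — the G-plus base-pair fraction of the same
  segmentation (`gplusFraction`) — is the recommended input.
* Percentages round halves away from zero (`percentOf`), one convention for
  every table.

## Cross-species comparison

GO enrichment is the classical hypergeometric upper tail over a stated gene
universe with BH correction at FDR < 0.01; terms annotating no selected
gene are skipped. No ancestor propagation is applied unless a child→parent
table is supplied (the original analysis used an unpublished enrichment
engine; the classical test is the transparent substitute).

For gene-set similarity under many-to-many orthology, both selected sets
are reduced by the iterative block-join rule: blocks start as singletons
and two blocks of one species merge whenever they are linked to a common
block of the other, until fixed point — equivalently, connected components
of the bipartite orthology graph, which is what the test oracle checks.
The 2×2 table uses the human-side linked-block count a (the mouse-side
count a′ is reported alongside), unlinked human blocks b, unlinked mouse
blocks c, and a universe N = number of equivalence classes of the union of
both full universes under the complete relation (a linked block pair counts
once). The Fisher test is one-sided (greater) throughout, since the
question is over-similarity; under strict 1-1 orthology the construction
provably reduces to the classical gene-level Fisher test, and the tests
check that reduction.

## The synthetic world

The generators produce every input the pipeline consumes, each from its own
RNG stream keyed by (seed, generator name), so outputs are byte-stable and
adding generators never perturbs existing ones. Defaults state the
validation world: a 1 Mb i.i.d. genome at GC 0.41, 3 cell types × 100
non-overlapping peaks (150–400 bp, exponential signal values), one
structure planted at 30 copies inside the target cell type's peaks, 50
genes with 1–3 exons and an exon mask, a 15-label segmentation hitting a
requested G-plus bp fraction (greedy assignment over randomly ordered
segments, accurate to one segment length), block-structured orthology
matching a requested size spectrum exactly, and GO annotations at base rate
0.02 with planted terms over-annotated by a stated factor.

The synthetic motifs are width-10 consensus matrices (97 counts on the
consensus base): sharp enough that sampled words nearly always clear the
balanced threshold, with a background false-positive rate near 3.5e-3 per
window. The consensus words GGAACGTCCA / CACGATTGAG were chosen by
measuring spurious-hit rates around planted composites; word pairs sharing
flanking substrings create systematic shifted near-matches (one candidate
pair produced an artifact structure in over half the planted sites), and
the chosen pair keeps the worst such artifact at ~20% of sites — weak
enough never to rival a 30-copy planted signal. Planted words are *sampled*
from the motif model, so recovery is high (≥90%) but deliberately not
exact.

What the generators do **not** emulate: real DNase signal shapes, ChromHMM
transition structure, sequence composition heterogeneity (isochores,
repeats), or GO DAG topology. A green planted-recovery test therefore
establishes that the statistics find what they are defined to find at
realistic signal-to-noise, not that they would rank real biological dimers
identically.

## Pipeline and reproducibility

`runPipeline` executes stages scan → discover → match → context → xspecies
from a config (R list or JSON; JSON stands in for YAML, which has no parser
in this package's dependency set), writing one TSV per product with a `#`
header carrying a config hash and the seed. Deterministic stages are
byte-identical across reruns of one config; `summarizeRun` rebuilds the
report tables (structure × cell-type breakdown, within-gene fractions,
Δ × type contingency, state-group histogram) from the files, recomputing
percentages from stored counts.

## Known limitations

* Genome-scale results from the original study (prediction counts, table
  totals, cross-species p-values) require the real ENCODE/TRANSFAC inputs,
  which are out of scope; the package checks their *reporting arithmetic*
  and validates the machinery on planted synthetic data.
* The enrichment statistic is a documented substitute (see above), so
  p-values are not comparable to the original tool's output, only the
  interface and ranking role are.
* `buildPartition` is quadratic in the worst case for pathological block
  chains; fine at gene-set scale.
* The binding-site layout defaults are a transcription of a published
  figure, not published coordinates; treat classifications as
  layout-relative.
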