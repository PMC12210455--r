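---
title: "Methods: detecting and profiling giant-virus endogenizations with geveR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and profiling giant-virus endogenizations with geveR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geveR)
```

## The problem

Giant viruses (NCLDVs) leave fragments of their genomes integrated in the
nuclear genomes of protists. These giant endogenous viral elements (GEVEs)
are typically recent, strain-specific, epigenetically silenced, and gradually
shredded by mutation, duplication and mobile-element colonization. Comparing
two chromosome-scale assemblies of closely related strains makes this process
visible: viral insertions show up as divergent (unalignable) regions of one
strain, clustered near chromosome ends, hypermethylated, transcriptionally
quiet, and densely packaged in Hi-C maps. geveR packages that comparison as a
pipeline of small, independently tested operations, and ships a synthetic
two-strain generator with planted truth so every stage can be validated end
to end without external data.

## Candidate calling

Queries are the annotated genes plus all intergenic ORFs of at least 150 nt,
taken stop-to-stop on both strands and three frames with **no start codon
required** — degraded, pseudogenized viral fragments rarely retain intact
gene starts. Open stretches may abut intergenic-interval boundaries, and
ambiguous codons are treated as stops (and counted), which is conservative:
an N-run can only split an ORF, never create one.

For each query, homology hits are filtered (e-value ≤ 0.001; all hits to the
host's own genus removed so recent transfers are not masked by self-matches;
subjects without a taxonomy record dropped and reported), deduplicated to the
best hit per subject, and ranked by bitscore, then e-value, then subject id.
A query becomes a viral candidate when its top hit is viral
(`best_hit_viral`) or when viruses are half or more of its top ten hits
(`majority_vote`). Decisions we had to make where the rule under-specifies:

- **Vote window after filtering.** The top ten are counted *after* e-value,
  self-genus and per-subject deduplication — duplicate HSPs would otherwise
  double-count a single subject, and self-genus hits are explicitly excluded
  from consideration.
- **Short rankings.** With `n < 10` surviving hits the quorum is
  `ceiling(n/2)`, the natural reading of "half or more". A consequence found
  by randomized testing: the candidate set is then *not* monotone in the
  e-value cutoff (removing bottom-ranked cellular hits can shrink the window
  and create a majority; removing a weak rank-1 cellular hit can expose a
  viral best hit). The test suite asserts the properties that do hold:
  rankings shrink order-preservingly under tightening, queries with no viral
  hit are never called, and all-viral queries are called whenever any hit
  survives.
- **Viral status** is `superkingdom == "Viruses"` in the taxonomy mapping.

## Conservation and viral regions

A candidate is `conserved` if its span overlaps at least one base of any
whole-genome-alignment block ("wholly or partially" alignable),
`non_conserved` if it lies entirely within the union of alignment GAP
records, and `unresolved` otherwise — the third status keeps the partition
exhaustive for genes beyond alignment termini or on unaligned scaffolds.
When blocks and gaps overlap, conservation wins.

Divergent regions are maximal concatenations of GAP, DUP (duplication) and
JMP (translocation) records that overlap, abut, or fall within `merge_slack`
of one another. `merge_slack` defaults to 0 ("contiguous" read literally) and
is configurable because the original concatenation procedure is not
published. INV and BRK records never join a region and block a merge when
they span the junction. The construction is idempotent and order-independent
(both property-tested). A region is **viral** when at least one full
candidate gene lies inside it — genes straddling a boundary do not count.
Manual curation of boundaries is supported, not automated: the pipeline emits
GC-shift tracks and editable region tables rather than guessing at
GC/gene-density heuristics.

Hallmark completeness scores each viral region for MCP, A32 ATPase, polB,
VLTF3 and SFII hits at e-value strictly below 1e-5 ("below" is strict, and
boundary-tested). In both real and simulated data no insertion carries a
full suite; the generator plants only MCP/A32/polB hits for this reason.

## Silencing profile

Methylation level of a CpG site is the fraction of methylated reads covering
it; sites are emitted strand-combined. A gene's level is the **unweighted
mean** over its sites with coverage ≥ 5 (the site-wise reading of "average
across all CpGs"; a pooled-read alternative sits behind `pooled = TRUE`).
The coverage floor is our choice — single-molecule per-site calls are noisy
below ~5 reads and no floor is prescribed; genes with no usable site are
excluded from classification and counted, never guessed. A gene is
*methylated* at mean ≥ 0.05, inclusive at the boundary. The rolling
methylation track uses 5,000 bp windows; only the window size is prescribed,
so the step defaults to 1,000 bp. Expression uses TPM computed from counts
and effective lengths (sums to 1e6 whenever any count is positive) and
log2-coverage in 2,500 bp windows with a +1 pseudocount, since zero-coverage
windows are the norm inside suppressed regions. Category comparisons use
Welch's unequal-variance t-test: viral and host gene groups differ strongly
in variance, and only "t-tests" is prescribed. Zero-variance degenerate pairs
are flagged rather than silently NaN'd. P-values are reported unadjusted
(matching the source analysis); apply `p.adjust` downstream if many
categories are compared.

## Genomic context

- **Telomeres.** Arrays are maximal runs of ≥ 3 consecutive unit-length
  windows, each within 1 mismatch of TTAGGG (either orientation); purity is
  the exact-unit fraction and purity < 1 defines "degenerate". The mismatch
  and run thresholds are our operationalization — no quantitative definition
  of a degenerate telomeric repeat is prescribed. Detection is
  reverse-complement symmetric (property-tested).
- **Sub-telomeric bias.** Mean normalized distance to the nearest chromosome
  end (`min(start, L - end)/L`, in [0, 0.5]) against a permutation null that
  redraws each feature uniformly on its own chromosome. A permutation test
  was chosen because the source analysis plots distance distributions without
  naming a test; it makes no distributional assumptions, and its p-values are
  calibration-tested for super-uniformity.
- **Mobile elements.** Pearson chi-square on the class × context table
  (viral region / other divergent / conserved background, assigned by element
  midpoint), with a fixed-margin Monte Carlo p-value when any expected count
  drops below 5.
- **Similarity links.** Region pairs are anchored by shared region-unique
  15-mers (k-mers with ≤ 2 distinct letters masked, approximating a DUST
  low-complexity filter), anchors on one diagonal are chained, extended
  ungapped, and scored by percent identity (defaults: span ≥ 500 bp,
  identity ≥ 80%). This desk-scale stand-in for an all-vs-all BLAST is
  validated against a global-alignment oracle under 10% substitution
  divergence; indel-rich homology is beyond the single-diagonal chain and is
  a known limitation.
- **Hi-C.** Expected contacts at separation *s* are the mean over all bin
  pairs at *s*, zeros included — the simplest detrend that removes the
  distance trend exactly (per-diagonal O/E means are 1, property-tested).
  No ICE/KR balancing is applied. A region's compaction score is log2 of the
  mean off-diagonal O/E among its bins; enrichment over matched random
  regions is assessed by permutation.

## The synthetic world

`simulation_config()` states the world once; its defaults are the conditions
the analysis assumes, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `background_divergence` | 0.15 /site | two strains at ~85% average identity |
| `chromosome_lengths` | 4 × 1.25 Mbp | 5 Mbp per strain: desk-scale chromosome-like scaffolds |
| `n_viral_insertions_per_strain` | 10 | tens of multi-gene strain-specific insertions |
| `insertion_length` | 20–80 kbp | multi-gene viral DNA chunks |
| `subtelomeric_bias` | 0.8 (terminal 10%) | insertions disproportionately near chromosome ends |
| `duplication_fraction` | 0.3 | partial, slightly diverged second copies scattered elsewhere |
| `mobile_element_rate` | 2 /region | host elements colonizing viral regions |
| `methylation_background_mean` / `viral_mean` | 0.02 / 0.8 | low host background vs hypermethylated insertions |
| `expression_background` / `viral` | 200 / 5 counts | transcriptional suppression of viral genes |
| `methylation_coverage_mean` | 20 (Poisson) | typical long-read depth; binomial methylated counts |
| `hit_noise` | 0.02 | taxonomic mislabeling; the source of "conserved viral candidates" |
| `telomere_units` | 50 × TTAGGG | canonical caps; strain B's mutated caps are naturally degenerate |

Strain A is the ancestral sequence plus its own insertions; strain B is the
ancestor mutated i.i.d. per site (Jukes–Cantor-style uniform replacement,
no background indels — the simplest model matching the identity summary)
plus its own insertions. The "alignment" (blocks, GAP/DUP/JMP records) is
derived analytically from the simulation history rather than by running an
aligner: that removes the external-tool dependence and makes the truth
exact. Insertion diff records are deliberately fragmented into abutting
GAP/DUP/JMP pieces (gene-bearing pieces always GAP) so region concatenation
is actually exercised. Orphan genes planted inside insertions receive no
homology hits, mirroring the ORFan-rich composition of real insertions.
Insertion ages and duplication rates are free parameters, not estimates —
no quantitative values exist for them.

What the generator does **not** emulate: realistic sequence composition
beyond GC contrast (codon structure, repeats beyond planted elements),
read-level errors, indel divergence, polyploidy/aneuploidy,
allele-specific insertions, and assembly artifacts. A green planted-truth
test therefore establishes that the *operations* implement their rules
correctly and compose, not that the thresholds are optimal for any real
genome.

## Numerical choices and degenerate inputs

Coordinates are 0-based half-open everywhere internally; GFF3 conversion
happens only at I/O. Ranking ties break by e-value then subject id, making
candidate tables fully deterministic. Percentages in conservation summaries
are rounded to the nearest integer (the reporting convention of the
source counts); a zero total reports `NA`. Permutation p-values use the
add-one estimator `(1 + #{null ≤ obs})/(n + 1)`, never exactly zero. All
stochastic stages draw seeds derived from one master seed via
`derive_seed()`, so stages are reproducible independently and jointly.
Empty inputs (no hits, empty chromosome, all-zero counts or contact
matrices) return empty-but-typed results rather than errors; impossible
configurations (negative slack, step 0, insertion longer than a chromosome)
error immediately.

## Known limitations

- Conservation uses nucleotide-level alignability as a proxy; as in the real
  analysis, duplications and partial deletions blur the conserved /
  non-conserved boundary.
- The hallmark scan, similarity links and compaction scores operate on
  provided tables and binned matrices; they do not re-run homology searches,
  aligners or Hi-C normalization.
- The CLI covers simulation, validation, the orchestrated run and the main
  per-stage commands; plotting is intentionally out of scope (tables are
  plot-ready).
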