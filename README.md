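# geveR

Genome-wide detection and epigenomic characterization of **giant endogenous
viral elements (GEVEs)** — sequences from nucleocytoplasmic large DNA viruses
(NCLDVs, "giant viruses") integrated into the nuclear genome of a unicellular
host. The package implements, as tested reusable building blocks plus an
orchestrated pipeline, the comparative analysis used to characterize viral
endogenizations in two closely related host strains (e.g. two *Acanthamoeba*
strains at ~85% average nucleotide identity):

1. **Candidate calling** — intergenic ORF extraction (≥ 150 nt, stop-to-stop,
   no start codon required) and classification of genes/ORFs as viral
   lateral-gene-transfer candidates from ranked homology hits. A query is
   retained when its best hit (after removing self-genus hits and hits with
   e-value > 0.001) is viral, or when viruses make up half or more of its top
   ten hits (quorum `ceil(n/2)` when fewer survive).
2. **Conservation and viral regions** — candidates are `conserved` if they
   overlap ≥ 1 bp of a whole-genome-alignment block, `non_conserved` if fully
   inside the union of alignment gaps; contiguous gap/duplication/translocation
   records are concatenated into *divergent regions*, flagged *viral* when at
   least one full candidate gene lies inside; viral hallmark genes (MCP,
   A32 ATPase, polB, VLTF3, SFII; e-value < 1e-5) are tallied per region.
3. **Silencing profile** — per-CpG methylation level = methylated reads /
   coverage; a gene is *methylated* when its mean site level is ≥ 5%;
   rolling 5,000 bp methylation and 2,500 bp log2 expression-coverage tracks;
   TPM (`1e6 · rate_g / Σ rate`, `rate_g = count_g / length_g[kbp]`); Welch
   t-tests across viral/non-viral × conserved/non-conserved categories.
4. **Genomic context** — telomeric TTAGGG array detection (canonical and
   degenerate), permutation test for sub-telomeric enrichment, chi-square on
   mobile-element composition by context, GC-shift tracks, k-mer-anchored
   nucleotide-similarity links between regions, and Hi-C observed/expected
   detrending with per-region compaction scores.
5. **Synthetic strain pairs** — a first-class generator
   (`simulate_strain_pair()`) producing two related genomes with planted,
   fully known ground truth (insertions biased toward chromosome ends,
   hypermethylated and transcriptionally suppressed viral genes, mobile
   elements colonizing viral regions, analytic alignment blocks/diffs,
   Hi-C matrices with elevated intra-insertion contacts), and emitters for
   every evidence-file dialect the pipeline reads.

## Worked example

```r
library(geveR)
cfg <- simulation_config(seed = 42, n_chromosomes = 2,
                         chromosome_lengths = 400000,
                         n_viral_insertions_per_strain = 3)
sim <- simulate_strain_pair(cfg)
evidence <- file.path(tempdir(), "evidence")
emit_evidence_files(sim, evidence)
reports <- run_pipeline(evidence, file.path(tempdir(), "out"),
                        pipeline_config(seed = 42))
r <- reports$strainA
r$conservation
#>   total conserved non_conserved unresolved pct_conserved
#> 1    62         3            59          0             5
subset(r$regions, is_viral, c(region_id, chrom, start, end, n_full_viral_genes))
#>                region_id chrom  start    end n_full_viral_genes
#> 1  dr_strainA_chr1_49330  chr1  49330  98578                 17
#> 2 dr_strainA_chr1_375550  chr1 375550 447148                 32
#> 3  dr_strainA_chr2_44324  chr2  44324  79584                 10
r$methylated_fractions
#>        category n_classified n_methylated pct_methylated n_excluded
#> 1     non_viral          285           27           9.47          0
#> 2         viral           62           59          95.16          0
#> 3     conserved          261            0           0.00          0
#> 4 non_conserved           86           86         100.00          0
```

62 of the strain's genes are called viral candidates; 59 are strain-specific
(the 3 "conserved" calls are planted taxonomic mislabels at the generator's
2% hit-noise rate — the analogue of eukaryote-to-virus back-transfers that
make real conserved candidates suspect). The three planted insertions are
recovered as viral regions at their exact coordinates. 95% of viral genes are
methylated versus 9% of host genes, and non-conserved genes are uniformly
methylated. Expression tells the same story (`r$comparisons`): non-conserved
viral genes average log2(TPM+1) = 5.8 versus 11.4 for conserved host genes
(Welch p = 2.5e-29). Hi-C compaction of the planted insertions exceeds matched
random spans (`r$compaction$observed_mean` = 1.23, permutation p = 0.005), and
no region carries a full hallmark suite (`r$hallmarks$full_suite` all FALSE).

A command-line driver wraps the same steps:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "gever.R", package = "geveR"))') \
    simulate --out evidence --seed 42
Rscript .../gever.R validate --dir evidence
Rscript .../gever.R run-all --dir evidence --out results
```

## Layout

- `R/` — implementation (simulation, I/O dialects, candidate calling,
  conservation/regions, silencing, genomic context, pipeline).
- `tests/testthat/` — unit, property and oracle-equivalence suites plus
  `test-acceptance.R` (arithmetic identities, oracle equivalence on ≥ 100
  random fixtures per operation, statistical calibration, end-to-end
  planted-truth recovery at the default 2 × 5 Mbp scale, boundary fidelity).
- `vignettes/gever-methods.Rmd` — model, assumptions, parameter rationale,
  and limitations.
- `inst/cli/gever.R` — command-line entry point.
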