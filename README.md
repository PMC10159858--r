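# bloodsift

Tools for a question that taxonomic classification alone cannot answer: does
a low-biomass blood metagenome contain genuine microbial signal, or only
reagent contamination and classification noise?

Deeply sequenced blood libraries from healthy donors yield a few thousand
microbial read pairs against hundreds of millions of host reads. At that
level, reagent-borne DNA (the "kitome"), batch-specific laboratory
contamination and read misclassification dominate naive species lists.
bloodsift implements the full inference chain used to separate signal from
artifact, for anyone analysing blood or other host-dominated metagenomes:

- **Presence calling** — species present only if read pairs
  $c > 10$ *and* relative abundance $c/\text{total} > 0.005$ (both
  configurable; entries at or below the thresholds are zeroed).
- **Batch-aware decontamination** — four sequential filters over laboratory
  batch metadata: batch prevalence (> 25% in one batch and > 2× every other
  batch of ≥ 100 samples), within-batch correlation (Spearman ρ > 0.7 on
  centred log-ratio abundances with a known contaminant), multi-batch
  detection (genuine species must appear in ≥ 2 batches of every reagent
  variable), and a 100-read maximum-count artifact filter.
- **Enrichment randomization tests** — 1,000 random species sets of the
  post-filter size, drawn from the pre-filter list, test whether survivors
  are depleted of known sequencing contaminants and enriched for
  blood-culture and human-associated species (null distribution exactly
  hypergeometric).
- **SparCC co-occurrence networks** — basis correlations from compositional
  counts via log-ratio variances, thresholded edge lists, and cross-cohort
  edge intersection.
- **Replication-rate analysis** — coverage peak-to-trough ratio
  (PTR = peak/trough of median-smoothed 10-kb binned coverage) with
  origin/terminus localization, cross-validated by the cumulative GC skew,
  and a replication call for eligible genomes (≥ 1,000 assigned read pairs,
  PTR above threshold).
- **Phenotype association screen** — per-cohort Fisher / Mann-Whitney tests
  of presence against host phenotypes, one pooled Benjamini-Hochberg pass
  over all cohorts and both tests, plus a separate family of derived health
  indicators.
- **Synthetic cohorts with planted truth** — batch-structured contaminants,
  sporadic genuine taxa, replication and skew signatures, and phenotype
  effects, for benchmarking every stage.

## Worked example

Simulate a 2,000-sample, 4-cohort population with 30 planted batch
contaminants and 20 sporadic genuine taxa, then run presence calling and the
decontamination chain:

```r
library(bloodsift)

sim      <- simulate_cohort_counts(simulation_config(seed = 1))
counts   <- qc_samples(sim$counts)          # drop samples with < 100 microbial reads
presence <- call_presence(counts)           # reads > 10 AND abundance > 0.005
presence
#> presence_matrix: 2000 samples x 95 species
#>   thresholds: reads > 10 AND/OR RA > 0.005 (rule = both)
#>   present entries: 39086 (20.57% of matrix)

report <- run_decontamination(presence, sim$meta)
report
#> decontam_report: 95 species before filtering
#>   after prevalence : 65 species
#>   after correlation: 65 species
#>   after batch      : 35 species
#>   after read_count : 35 species
#>   110 contaminant calls, 35 survivors
```

The species list shrinks stage by stage, and scoring the calls against the
planted truth shows the chain recovers all 30 contaminants without touching
the genuine taxa:

```r
flagged <- unique(report$calls$species)
sum(sim$truth$contaminants$species %in% flagged)   # 30 of 30 planted contaminants
sum(sim$truth$genuine$species %in% flagged)        # 0 of 20 genuine taxa
```

(The 35 survivors are the 20 genuine taxa plus 15 simulated ubiquitous
reagent species — uniform, batch-independent contamination is exactly what
batch-aware heuristics cannot remove, and the generator keeps it honest.)

Replication analysis on a simulated coverage track with a planted
peak-to-trough ratio of 1.8:

```r
track <- simulate_coverage(2e6, ptr = 1.8, ori = 4e5, ter = 1.5e6,
                           mean_depth = 25, seed = 1)
res <- call_replicating(estimate_ptr(bin_and_smooth(track)),
                        assigned_reads = 5000)
res
#> ptr_result [sim_ptr1.80]: PTR 1.744 (peak 32.56 @ 375000 bp, trough 18.67 @ 1475000 bp)
#>   eligible: TRUE, replicating: TRUE
```

The estimated PTR (1.744) and origin/terminus positions land within a few
percent of the planted values; a genome with PTR 1 would be flagged
degenerate and never called replicating.

Real data enter through the same functions: `parse_kraken2_report()` /
`read_count_matrix_tsv()` for profiles, `read_batch_metadata()`,
`read_annotation_db()`, `read_phenotypes()`, `read_coverage()` for the rest,
and `run_pipeline(validate_config("config.yaml"))` (or the thin CLI at
`inst/cli/bloodsift.R`) to orchestrate everything with a machine-readable
run report.

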