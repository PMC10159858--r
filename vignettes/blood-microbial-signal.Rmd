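---
title: "Detecting genuine microbial signal in low-biomass blood metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genuine microbial signal in low-biomass blood metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodsift)
```

## The problem

Blood from healthy donors is an extreme low-biomass sample: a deeply
sequenced library contains hundreds of millions of host read pairs and, after
host removal and taxonomic classification, typically only thousands of
microbial read pairs. At that signal level, three artifact sources dominate
what a classifier reports: reagent-borne microbial DNA (the "kitome"),
cross-batch laboratory contamination, and read misclassification. Deciding
whether anything genuinely microbial is present therefore requires an
inference chain, not a single threshold. bloodsift implements such a chain:

1. **Presence calling** from species-level read counts,
2. **batch-aware decontamination** using laboratory processing metadata,
3. **randomization tests** that ask whether the surviving species look like
   biology or like reagent flora,
4. **SparCC co-occurrence networks** and their cross-cohort intersection,
5. **replication-rate (PTR) analysis** of genome coverage with GC-skew
   cross-validation, and
6. a **host-phenotype association screen** with pooled multiple-testing
   correction.

A synthetic-data module plants known truth (contaminant homes, genuine
prevalences, replication parameters, phenotype effects) so that every stage
can be benchmarked end to end.

## Presence calling

Relative abundance of species $s$ in sample $i$ is
$a_{is} = c_{is} / \sum_s c_{is}$, the species read-pair count over the
sample's total microbial read pairs. A species is counted *absent* when its
abundance falls at or below either threshold; with the default conjunctive
rule, presence requires

$$c_{is} > 10 \quad\text{and}\quad a_{is} > 0.005 .$$

Both defaults are the standard values for this analysis; the count threshold
suppresses sporadic misclassification, the abundance threshold suppresses
proportional bleed-through from abundant organisms. Absent entries are set to
zero read counts, but abundances are *not* recomputed afterwards — the
denominator stays the sample's original microbial total, so zeroing one
species cannot promote another past the threshold. Samples with fewer than
100 microbial read pairs are removed before any of this.

The phrasing of joint thresholds admits an OR reading (absent when either
threshold fails) and an AND reading; `call_presence(rule = )` supports both,
defaulting to the stricter conjunction for presence.

## Decontamination

Four filters run in sequence; each stage sees only the survivors of the
previous one, and a species flagged anywhere is removed globally (the method
produces a single shrinking species list, not per-batch lists):

1. **Prevalence filter.** For every batch variable (cohort, extraction kit,
   library preparation kit, reagent lots, flow cell) and every batch with at
   least 100 samples: a species present in more than 25% of a batch's
   samples, and at more than twice its prevalence in *every* other eligible
   batch of that variable, is a batch-specific contaminant. Small batches
   are excluded from both sides of the comparison; a positive prevalence
   beats a zero comparator (a species exclusive to one large batch is
   called).
2. **Correlation filter.** Contaminants from one reagent lot co-occur.
   Candidate species whose centred log-ratio (CLR) abundances have Spearman
   $\rho > 0.7$ with any stage-1 contaminant, over the samples of that
   contaminant's batch, are also contaminants. CLR is
   $\ln(a_{is}) - \tfrac1D\sum_t \ln(a_{it})$ after replacing zeros with
   0.65 times the smallest nonzero abundance (multiplicative simple
   replacement). Because Spearman is rank-based within a fixed sample set,
   the zero-replacement constant barely matters; it is still recorded for
   reproducibility.
3. **Batch filter.** A genuine species must be detected in at least two
   batches of every reagent variable. The library preparation kit type is
   excluded by default (a variable dominated by a single level carries no
   discriminating information). Species detected in zero samples are flagged
   here as the degenerate single-batch case.
4. **Read-count filter.** A species never reaching 100 read pairs in any
   single sample is an analysis artifact — persistent trace assignments
   never exceeding background noise.

Every call records the evidence (prevalences, fold ratios, $\rho$, partner,
maximum reads) so the rule can be re-evaluated from the call itself.

To validate the outcome, `randomization_test()` draws 1,000 random species
sets of the post-filter size from the pre-filter list and compares annotation
proportions (likely sequencing contaminants, blood-culture detections,
human-associated species). The p-value is the plain fraction of draws at
least as extreme as the observation; the null distribution of
category-positive draws is exactly hypergeometric, which the tests exploit as
an oracle. Filters that work should deplete likely contaminants
(direction `less`) and enrich the other two categories (direction
`greater`).

## Co-occurrence networks

SparCC estimates correlations between *basis* (unobserved absolute)
abundances from compositional counts: per-sample fractions are drawn from a
Dirichlet posterior (counts + 1), log-ratio variances
$t_{ij} = \mathrm{var}\,\ln(x_i/x_j)$ are collected, basis variances
$\omega_i$ are solved from $\sum_j t_{ij} \approx (D-2)\,\omega_i + \sum_j
\omega_j$ (the sparsity assumption), and

$$\rho_{ij} = \frac{\omega_i + \omega_j - t_{ij}}{2\sqrt{\omega_i\omega_j}},$$

clipped to $[-1, 1]$. The strongest pair above 0.1 is iteratively excluded
from the system and the solve repeated (10 rounds), and the final matrix
averages 20 Dirichlet resamples. These internals (pseudocount 1, 20 draws,
10 exclusion rounds at 0.1) follow the published algorithm's conventions and
are exposed as arguments. Networks keep edges with $|\rho|$ strictly above a
threshold (0.05 / 0.2 / 0.3 by default); per-cohort networks can be
intersected on unordered species pairs — consistent biology should reproduce
edges across cohorts, reagent artifacts should not. Networks use only
samples with at least two present species. With `n_draws = 0` the estimator
runs on point-estimate fractions, which is the deterministic path used for
exact oracle comparisons (and makes duplicated species columns hit
$t_{ij}=0$, $\rho = 1$ exactly).

## Replication analysis

A replicating bacterial population has more genome copies near the
replication origin than the terminus, so read coverage along a circular
genome is sinusoidal in log-space: maximal at *Ori*, minimal at *Ter*.
Coverage is averaged in 10-kb bins and smoothed with an 11-bin circular
running median (robust to spikes from mobile elements or conserved
repeats; both parameters configurable). The peak-to-trough ratio is

$$\mathrm{PTR} = \max_b \bar d_b \,/\, \min_b \bar d_b \ \ge 1,$$

with Ori/Ter at the argmax/argmin bin midpoints. A piecewise-linear
log2-coverage fit between Ori and Ter yields an $R^2$ quality score so flat
or chimeric coverage can be rejected. Eligibility for a replication call
requires at least 1,000 assigned read pairs in the sample; the default call
threshold is PTR > 1.1 rather than the literal > 1, a guard band because
Poisson noise on flat coverage produces ratios marginally above 1 (the
max/min construction is biased upward); `ptr_threshold = 1` restores the
literal rule, and the two agree on any clearly replicating genome.

GC skew provides an orthogonal locator: per 10-kb window,
$(G - C)/(G + C)$, accumulated along the genome and detrended by the line
through the cumulative series' endpoints (the circular closure constraint).
Strand-biased composition makes the detrended cumulative skew minimal at Ori
and maximal at Ter — anti-phase with coverage. The degeneracy guard compares
the cumulative range against $5\,\hat\sigma\sqrt{W}$, the scale of a random
GC-skew walk over $W$ windows, with $\hat\sigma$ estimated from circular
first differences of the window skews (differencing removes the
piecewise-constant replication signal, leaving sampling noise).

## Association screen

Within each cohort, every surviving species is tested against host
phenotypes: Fisher's exact test for categorical phenotypes (sex, ancestry as
a single 2×k table), Mann-Whitney U for continuous ones (age, BMI, total
cholesterol, triglycerides, systolic/diastolic blood pressure). Species must
be present in at least 50 samples overall to be tested; samples with missing
phenotype data are excluded per test. Benjamini-Hochberg correction is
applied once across *all* cohorts and both test types. Derived indicators —
elderly (age ≥ 65), obese (BMI > 30), high triglycerides (> 2.3 mmol/l),
high cholesterol (≥ 6.3 mmol/l), high blood pressure (SBP ≥ 130 and DBP ≥
80) — form a second family with its own correction pass. Significant hits
are annotated with the number of cohorts in which they replicate, since real
population-level associations should not be cohort-private.

Small-sample Mann-Whitney p-values are computed by exact enumeration of
group labelings with mid-ranks (total n ≤ 10), doubling the smaller tail —
exact even under ties, where the standard implementation falls back to an
approximation; larger samples use the continuity-corrected normal
approximation with tie-corrected variance. Fisher tests on 2×k tables with
large totals (k > 2, n > 200) use a seeded Monte-Carlo estimate.

## The synthetic cohort generator

`simulate_cohort_counts()` emulates the structure that matters to the
filters, at desk scale. Defaults, which are the package's benchmark
conditions: 2,000 samples in 4 equal cohorts; 4 further batch variables
(extraction kit, library preparation kit, SBS lot, flow cell) with 4 batches
each, assigned in contiguous blocks with variable-specific offsets so that
variables are mutually confounded the way real processing runs are; 20
genuine taxa at prevalence uniform in [0.001, 0.05]; 30 contaminants at 0.4
home-batch prevalence and 0.05 elsewhere, with presence and abundance of
co-resident contaminants driven by a shared per-sample Gaussian latent
factor (copula correlation 0.8 — any monotone dependence suffices since the
correlation filter is rank-based); per-sample totals log-normal with median
6,000 and σ = 1; 30 misclassification-noise species never exceeding 10
reads; and 15 ubiquitous background species that absorb each sample's
remaining reads. When present, a planted species takes relative abundance
log-normal(log 0.03, 0.6), so it passes the presence thresholds in well over
90% of occurrences at these read totals.

What the generator deliberately does *not* model: read-level error and
misclassification structure (counts are planted directly), GC bias in
coverage, taxonomic ambiguity between related species, negative controls,
and contaminant load that anti-correlates with input biomass. Passing the
benchmarks therefore shows that the *inference rules* recover planted
structure under realistic sparsity and batch confounding — not that any
particular real dataset is clean. The background pool is itself a modelling
statement: uniform, batch-independent reagent flora is invisible to
batch-aware heuristics, and the generator keeps it so the benchmark cannot
silently reward over-aggressive filtering.

`simulate_coverage()` plants a piecewise-linear log2 expected depth
(peak/trough ratio exactly the requested PTR, mean scaled to the requested
depth) with Poisson bin noise; `simulate_genome_with_skew()` biases the G:C
balance by ±amplitude on the two replication segments. Phenotypes come from
plausible adult marginals (age uniform 21-80, BMI normal(24, 4) truncated at
14, lipids and blood pressure normal with population-typical means, 2%
missingness); a planted effect shifts a species' presence log-odds for
samples meeting a phenotype condition and redraws that column.

## Numerical and design notes

- **Determinism.** Every stochastic routine takes a seed and restores the
  caller's RNG state; the pipeline report is byte-identical across runs with
  the same config and seed. SparCC's Dirichlet path is seeded but consumes
  randomness in sample order, so exact sample-order invariance holds on the
  point-estimate path (`n_draws = 0`) and in distribution otherwise.
- **Boundaries.** "Fewer than 100 reads" keeps a 100-read sample;
  presence thresholds are strict (10 reads / 0.005 abundance are *absent*);
  the prevalence and correlation filters use strict `>`; the read-count
  filter's "at least 100 in one sample" is inclusive.
- **Degenerate inputs.** Zero-total samples are rejected before abundance;
  all-zero rows cannot be CLR-transformed; flat coverage yields PTR exactly
  1 with a degeneracy flag; batches with under 3 samples are skipped by the
  correlation filter with a warning; variables with fewer than two eligible
  batches are skipped by the prevalence filter.
- **Problem sizes.** The bundled benchmarks use 2,000-sample cohorts,
  2-Mb genomes in 10-kb bins, 500-sample/20-species SparCC instances, 1,000
  randomization draws and 50-replicate calibration loops — sizes at which
  every planted quantity is comfortably identifiable while the whole suite
  runs on a laptop.
- **Calibration honesty.** Under a global null with near-continuous
  p-values, Benjamini-Hochberg rejects *something* in about 5% of datasets
  (that is what FDR ≤ 0.05 means at the global null), so "no significant
  hits" calibration checks sit at that boundary by construction; runs with a
  single spurious adjusted hit in a small fraction of replicates are the
  expected behaviour of a correct implementation, not evidence of one
  that is broken.

## Known limitations

- The decontamination heuristics need informative batch metadata; with a
  single batch per variable (or none recorded) only the read-count filter
  has power.
- Uniform reagent contamination present across all batches is
  indistinguishable from a ubiquitous commensal by these rules.
- PTR assumes a single dominant replicating population on a finished
  circular genome; draft-genome (fragment-sorted) modes are out of scope.
- The association screen is marginal: no confounder adjustment beyond
  cohort stratification.
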