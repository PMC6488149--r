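---
title: "Methods: germline truncating-mutation burden testing in gene panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline truncating-mutation burden testing in gene panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelburden)
library(dplyr)
```

## The problem

Multigene panel testing screens a curated set of cancer predisposition
genes for damaging germline variants. Whether a panel is equally
informative across populations depends on whether the panel genes are
actually enriched for damaging variation in each population, over and
above that population's background rate of damaging variation. panelburden
implements this comparison for protein-truncating variants (PTVs): stop
gain, stop loss, frameshift indels, and canonical splice-site disruptions
— the class of variants whose damaging effect is least ambiguous across
populations, which matters because pathogenicity databases used to
classify missense variants are themselves biased toward European-ancestry
data.

The pipeline has four stages: (1) filter annotated variant calls down to
rare PTVs; (2) compute per-individual callable exposures from coverage
profiles; (3) estimate a population-specific background mutation rate and
test the gene panel for enrichment; (4) compare populations and pool
cohorts.

## The model

Within population $i$ with $n_i$ individuals, let $M_{ij}$ be the number
of filtered truncating mutation events observed exome-wide in individual
$j$, and $L_{ij}$ the number of positions in the capture regions that are
callable in that individual (read depth $\ge 15$ under the upstream
quality gates). The background rate is the pooled ratio

$$\hat\lambda_i = \frac{\sum_j M_{ij}}{\sum_j L_{ij}},$$

a rate per callable position, not a mean of per-individual ratios —
individuals with more callable territory carry proportionally more
weight, and the estimator is invariant to duplicating a cohort.

Let $m_{ij}$ and $l_{ij}$ be the corresponding panel quantities, with the
panel clipped to the capture territory ($l_{ij}$ counts panel positions
inside capture that are callable in individual $j$). Under the null
hypothesis that panel positions mutate at the background rate, the total
observed panel count $x_i = \sum_j m_{ij}$ is Poisson with mean
$\hat\lambda_i T_i$, $T_i = \sum_j l_{ij}$. `poisson_two_sided()` computes
the exact two-sided p-value under the minimum-likelihood construction:
the sum of Poisson probabilities of all outcomes no more probable than
$x$ (within relative tolerance $10^{-7}$). Several two-sided conventions
exist (doubling the smaller tail, central intervals); the
minimum-likelihood sum is used because it is the construction of
`stats::poisson.test`, and the two agree to machine precision in our
tests.

`expectation_interval()` draws the "box of random expectation" around the
expected count: the central interval $[lo, hi]$ with
$P(X \le lo - 1) \le 0.025$ and $P(X \le hi) \ge 0.975$. By construction
the interval always holds at least 95% mass (discreteness makes it
conservative; the acceptance checks measure 95.5% at $\mu = 100$ and
97.9% at $\mu = 5$).

Treating $\hat\lambda_i$ as known when forming the null mean ignores its
sampling error; this is deliberate and mirrors the exposure-offset
construction of the method. Because $T_i/\!\sum_j L_{ij}$ is of order
1/300 at the default panel-to-exome ratio, the estimation error of
$\hat\lambda_i$ is negligible next to the Poisson noise in $x_i$.

Between-group contrasts use two standard tests:

* **Fisher exact** on a 2×2 table. Two constructions are reported side by
  side because "mutation rate" can be read two ways: events vs non-event
  callable positions per group (`events_vs_exposure`, the default — a
  rate-per-position contrast), and carriers vs non-carriers
  (`carriers` — a prevalence contrast, a carrier being an individual with
  $m_{ij} \ge 1$).
* **Mann–Whitney** on per-individual exome-wide counts $M_{ij}$, for the
  question "which population carries the heavier exome-wide burden".
  Counts are small integers with heavy ties, so midranks are used, and
  the exact permutation null of the midrank sum is enumerated whenever
  both groups have at most 10 individuals, ties included; larger groups
  use the normal approximation with tie-corrected variance and no
  continuity correction. Enumerating in the tied case (rather than only
  when ties are absent) keeps the small-sample path exact for count data,
  where ties are the norm rather than the exception.

Unadjusted two-sided p-values at the 0.05 level are the primary output; a
Bonferroni column across populations is emitted for transparency but not
used for significance calls.

### Meta-analysis

Cohorts genotyped on different capture kits are harmonized by restricting
to the kit intersection, or to CCDS when an external cohort's capture
composition is unknown (`ccds_restrict`); restriction applies to both
numerators (variants) and denominators (exposures), so counts and
exposures can only shrink. Pooling then sums $\sum m$, $\sum l$,
$\sum M$, $\sum L$ across cohorts per population and applies the same
exact tests to the pooled aggregates. Pooling counts and exposures —
rather than combining per-cohort p-values by Fisher's method — is chosen
because the sufficient statistics of every test here are count/exposure
pairs, for which pooling preserves exactness; a population present in
only one cohort is excluded from pooling with a warning.

## The filter cascade

Filters run in a fixed order; each removed variant is charged to exactly
one filter, and the accounting identity *input = removed + surviving*
holds at every stage:

| order | filter | rule |
|---|---|---|
| 1 | genotype missingness | genotype depth < 3 → missing; site missing rate > 0.1 → drop |
| 2 | truncating class | keep splice_site, frameshift_indel, stopgain, stoploss |
| 3 | allele frequency | any reference-population AF > 0.02 → drop |
| 4 | long indel | indel length > 20 bp → drop |
| 5 | carrier depth | carrier's depth < 15 → event dropped; variant dropped when no carrier qualifies |
| 6 | masks | position in tandem-repeat or segmental-duplication mask → drop |
| 7 | restriction | position outside capture (and CCDS in harmonized mode) → drop |

All inequalities are strict as stated: a site at missing rate exactly 0.1,
an AF of exactly 0.02, a 20 bp indel, and a depth of exactly 15 are all
retained. An AF absent from every source never removes a variant —
absence of evidence of commonness is not evidence of commonness, and the
filter exists to exclude *known* common variants.

Two interpretation choices deserve explanation:

* **Carrier depth is per-event.** The depth ≥ 15 requirement is applied
  to the carrier's genotype, not to a site-level average: a variant seen
  in two individuals at depths 14 and 40 contributes one event, not zero
  or two. A site-wide reading would contradict the per-individual event
  accounting of the rate estimator, where each event must be attributable
  to one individual with adequate evidence.
* **Masks act on variants, not denominators.** $L_{ij}$ counts all
  callable capture positions, including masked ones, while variants in
  masks are removed. The alternative (subtracting masks from exposures)
  is defensible but changes $\hat\lambda$ by the masked fraction; the
  literal reading keeps the denominator a pure coverage quantity.
  Regions masks cover are a small fraction of the capture, so the choice
  is second-order.

Consequences and allele frequencies are consumed from annotation INFO
keys (ANNOVAR refGene/popfreq dialect by default, remappable via
`vcf_key_map()`); the package never recomputes transcript-level
consequences. Multi-allelic records are decomposed to one record per ALT
allele before any filter, and the missingness rule applies to every
decomposed record. Contig naming must agree across all inputs; a
`chr1`-vs-`1` mismatch is an explicit error, never silently harmonized,
because silent renaming corrupts interval arithmetic.

## Exposures

Coverage profiles are *inputs*: per-sample BED intervals of positions
passing depth ≥ 15 with mapping quality > 20 and base quality > 13,
anomalous read pairs ignored (or a per-base depth table converted at a
stated threshold with `depth_to_intervals()`). The package does not parse
alignments; the quality gates are part of the profile-production
contract. All interval algebra is 0-based half-open, strand-agnostic, and
delegated to GenomicRanges behind the `region_set` tibble surface, with a
VCF variant's membership tested at its anchor base (`pos - 1`).

## The synthetic-data generator

`simulate_cohort()` emits a complete self-contained cohort: annotated
VCF, per-sample coverage BEDs, region BEDs (capture, 19-gene panel,
masks, CCDS), population table, and a ground-truth manifest. The
generative model is the analysis model run forward: individual $j$ of
population $i$ receives $\mathrm{Poisson}(e_i\,\lambda_i\,l_{ij})$ panel
events and $\mathrm{Poisson}(\lambda_i\,(L_{ij} - l_{ij}))$ off-panel
events, placed uniformly at random within that individual's callable
intervals — a homogeneous per-position rate with no hotspot structure,
matching the single-$\lambda$-per-population assumption of the test
itself. Coverage dropout removes a $U(0.1, 0.3)$ fraction of every
capture block per sample, a realistic range for exome capture
variability. All generated genotypes are heterozygous: an event is a
variant call in an individual, so zygosity does not enter the counting.

Default cohort conditions emulate a four-population early-onset TNBC
discovery cohort: 48/40/25/13 samples (White/Black/Hispanic/Asian), with
the Black population carrying the highest exome-wide truncating rate
(1.6e-7 per callable position ≈ 3.8 events per exome at 30 Mb and average
dropout) and panel enrichment factors 5/1/3/1. The event densities follow
the regime the analysis targets — low single-digit exome-wide events per
individual and at most about one panel event per individual — so under
these defaults the White and Hispanic populations show significant panel
enrichment while the Black population, despite the heaviest exome-wide
burden, shows none: the reversal pattern that motivates the analysis.

Decoy variants exercise each filter: one engineered high-missingness
site, one missense, one 25 bp insertion, one carrier at depth 14, one
variant inside the tandem-repeat mask, one in an inter-block gap, and a
configurable number of common contaminants (AF 0.05–0.5). Each decoy
fails exactly one filter; true events are annotated to pass all of them
(placed outside masks, AF absent or < 0.02, carrier depth ≥ 20). The
manifest records the intended disposition of every variant and the true
per-sample counts, so a correct pipeline must recover both exactly.
Frameshift events are generated as insertions only; deletions would
require reference-sequence bookkeeping that adds nothing to what the
length filter tests.

Determinism is a hard contract: every stochastic entry point takes an
explicit seed, and the same scenario and seed reproduce byte-identical
files.

### Calibration harnesses and problem sizes

`simulate_null_grid()` and `simulate_reversal_grid()` simulate at the
level of the generative model's sufficient statistics (per-sample
callable lengths and Poisson counts) rather than writing VCFs, because
only counts and exposures enter the tests; this makes $10^4$ replicate
cohorts cheap while remaining the same model — file-level equivalence is
established separately by the manifest round-trip checks. The study
conditions for the harnesses are fixed at 40 samples, exome rate
1.5e-6 per callable position, 30 Mb capture and 100 kb panel per sample,
dropout $U(0.1, 0.3)$; power and reversal scenarios use panel enrichment
5, with the reversal contrasting a rate-1.5e-6/enrichment-1 population
against a rate-1.0e-6/enrichment-5 population.

## Known limitations and numerical notes

* **The exact test is conservative at small expected counts.** The
  minimum-likelihood two-sided Poisson test at level 0.05 has achievable
  size well below the nominal level under discreteness: its exact size is
  ≈0.019 at $\mu = 1$, ≈0.033 at $\mu = 4.8$ (the default study
  conditions, where the Monte-Carlo rejection rate measures ≈0.034),
  ≈0.043 at $\mu = 20$, approaching 0.05 only for $\mu$ in the hundreds.
  Type-I error is therefore controlled (never above nominal) but a
  nominal-level rejection-rate band like 5% ± 1% is unattainable at
  desk-scale panel exposures; the calibration suite asserts and reports
  this honestly.
* Simulated cohorts have no linkage, no site-frequency spectrum beyond
  the rare/common dichotomy, no sex-chromosome ploidy handling, and no
  mutational hotspots; passing tests demonstrate correctness of the
  accounting and calibration of the tests under the homogeneous-rate
  model, not robustness to real-data artifacts such as mapping bias or
  batch effects in coverage.
* Position collisions between independently placed events are resolved
  by a deterministic +2 bp shift; at default event densities (hundreds of
  events over tens of Mb) collisions are vanishingly rare.
* No covariate adjustment, no gene-level tests, no variance-component
  (dispersion) tests: the unit of inference is the whole panel within a
  population.

## A worked example

```{r example}
cfg <- scenario_config(seed = 42)
sim <- simulate_cohort(cfg, dir = file.path(tempdir(), "cohort"))

run <- run_full(run_config(
  cohort = "discovery",
  vcf = sim$paths$vcf,
  coverage = dirname(sim$paths$coverage[[1]]),
  capture = sim$paths$capture,
  panel = sim$paths$panel,
  masks = c(tandem_repeat = sim$paths$tandem_repeat,
            segdup = sim$paths$segdup),
  populations = sim$paths$populations,
  fisher_reference = "White", mw_reference = "Black"))

run$filter$report
tidy(run$fit)
run$fit$pairwise
```

```{r plot, fig.width = 6, fig.height = 4}
autoplot(run$fit)
```
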