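---
title: "F-statistics under RAD-seq missing data: models, estimators and the dropout bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{F-statistics under RAD-seq missing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radfst)
library(dplyr)
```

Reduced-representation sequencing genotypes only the individuals whose
restriction fragments survive digestion, size selection and sequencing, so a
RAD-seq SNP table is riddled with holes — and the holes are not random.
A mutation in a restriction site silences the whole tag on that haplotype: a
*null allele*. Individuals carrying two null copies yield a missing call;
individuals carrying one are genotyped from the single surviving haplotype
and read as homozygotes. Both effects are tied to the locus's null-allele
frequency, which drifts among populations like any allele. The practical
question this package addresses: when you choose how complete a locus must
be to keep it (the *completeness cutoff*), how do F-statistics respond, and
how much of the response is missingness rather than locus count?

`radfst` provides the full chain needed to study that question on real or
simulated panels: a diploid multi-population genotype container with VCF /
genepop / TSV readers, the standard RAD filter regime, gene-diversity and
variance-component F-statistic estimators that handle missing data
explicitly, bootstrap and locus-subsampling machinery, genotype PCA, and an
island-model simulator with a mechanistic dropout model.

## The estimators

For a locus and population $k$ with $n_k$ genotyped individuals, let
$H_{O,k}$ be the observed heterozygote fraction and $p_{k,i}$ the sample
allele frequencies. The unbiased within-population gene diversity is Nei's
sample-size-corrected estimator

$$\hat H_{S,k} = \frac{n_k}{n_k - 1}\Big(1 - \sum_i p_{k,i}^2 -
\frac{H_{O,k}}{2 n_k}\Big),$$

which requires $n_k \ge 2$; populations with a single genotyped individual
at a locus are excluded *at that locus* (their frequency estimate carries no
within-population information, and the correction above is undefined). With
$np$ included populations, $\tilde n$ their harmonic-mean sample size and
$\bar p_i$ the unweighted mean frequencies,

$$\hat H_T = 1 - \sum_i \bar p_i^2 + \frac{\hat H_S}{\tilde n\, np}
- \frac{\hat H_O}{2 \tilde n\, np}, \qquad
F_{ST} = \frac{\hat H_T - \hat H_S}{\hat H_T}, \qquad
F_{IS} = 1 - \frac{\hat H_O}{\hat H_S}.$$

Multilocus values are **ratios of per-locus averages**, never averages of
per-locus ratios: low-diversity loci would otherwise dominate through noisy
ratios. A locus where a statistic is undefined ($\hat H_T = 0$, or fewer
than two populations typed) carries an explicit flag and is excluded from
the relevant mean — substituting 0 or 1 would manufacture exactly the
extreme-value pile-ups the package is meant to measure.

The Weir–Cockerham (1984) variance-components estimator $\theta$ is
provided as an alternative (`wc_theta()`), with the same $n_k \ge 2$
exclusion rule so the two estimators always see the same data. The two
differ in what they estimate: the gene-diversity $F_{ST}$ measures
differentiation *among the sampled populations* (under an island model with
$K$ demes its expectation is below the generating $F$ by a factor close to
$1 - 1/K$), while $\theta$ is approximately unbiased for $F$ itself. Both
recover $F = 0.10$ within $\pm 0.015$ on study-shaped panels in the test
suite, but confidence intervals meant to cover a *generating* parameter
should be built on $\theta$; the suite's coverage check does exactly that.

```{r estimators}
panel <- simulate_snp_panel(sim_config(n_loci = 2000, target_fst = 0.1, seed = 1))
multilocus_stats(per_locus_stats(panel$matrix))
wc_theta(panel$matrix)$overall
```

## The filter regime

`select_single_snp()` keeps the first SNP of each RAD tag (linked SNPs on an
~90 bp tag are near-duplicates), `filter_maf()` applies a strict
`> maf_min` threshold on the minor allele frequency pooled over all typed
individuals (the filter sits upstream of any population analysis, so it is
deliberately population-blind), and `build_dataset_family()` sweeps a
completeness gradient: cutoff $k$ keeps exactly the loci genotyped in at
least $k$ individuals. Percentages of individuals required are reported
rounded half-up to one decimal, the convention of the tables this mirrors.
MAF is evaluated once, on the full matrix, not per family member: the
family emulates one genotyping run filtered at different strictness, not
independent runs.

```{r family}
noisy <- apply_allelic_dropout(panel$matrix, panel$truth, seed = 2)$matrix
fam <- build_dataset_family(noisy, cutoffs = c(1, 10, 48, 77))
fam$summary
```

## What the simulator emulates — and what it does not

`simulate_snp_panel()` draws, per locus, an ancestral frequency from
Uniform(0.05, 0.5) (so panels pass a MAF > 0.05 filter by construction) and
deme frequencies from the Balding–Nichols Beta model
$p_k \sim \mathrm{Beta}\big(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\big)$,
whose expected $F_{ST}$ equals the target $F$ — chosen over coalescent
simulation precisely because it gives a closed-form target to test
recovery against. Genotypes are Hardy–Weinberg within demes. The default
shape is 12 demes of 8 diploids (96 individuals), the sampling design of
the field study this emulates. `simulate_ssr_panel()` is the multiallelic
Dirichlet analogue for microsatellite-like loci.

Three missingness mechanisms can be layered on a panel:

* `apply_mcar()` — every call missing independently at one rate; the
  neutral baseline. Completeness filtering of MCAR panels leaves estimates
  unbiased, which is what makes the dropout contrast attributable to the
  mechanism rather than to the filter.
* `apply_individual_missingness()` — per-individual rates, emulating
  library-quality differences between samples.
* `apply_allelic_dropout()` — the mechanistic model. Per locus an ancestral
  null fraction $q$ is drawn from `q_law` (default Uniform(0, 0.9), so
  per-locus missingness spans none to near-complete, as in unfiltered RAD
  tables); for each *allele background* and deme the within-background
  null fraction drifts by Balding–Nichols with the panel's own $F$. Two
  null copies silence the call; one leaves a false homozygote. Because
  null rates differ between backgrounds deme by deme, apparent allele
  frequencies are distorted deme-specifically — this is what inflates
  $F_{ST}$. The linkage is essential: a null drawn independently of the
  allele carried leaves apparent frequencies unbiased and produces *no*
  inflation, only a heterozygote deficit. High-$q$ loci are both the most
  biased and the most missing, so relaxing the completeness cutoff admits
  them and the multilocus $F_{ST}$ rises; the test suite asserts this
  direction on 20 seeded replicates, along with the pile-up of per-locus
  $F_{ST} > 0.975$ at the weakest cutoff.

Deliberately not modelled: sequence-level realism (reads, restriction-site
sequences, assembly artefacts), stepwise mutation for SSRs, linkage between
loci, selection, and any geography — demes are exchangeable. Passing tests
on these panels therefore show that the *estimators and the filter
interact with the dropout mechanism* as claimed, not that any particular
empirical dataset is free of other biases.

## Resampling

`bootstrap_ci()` resamples loci with replacement and reports closed
percentile intervals (percentile rather than BCa for transparency; B
defaults to 1000). `subsample_experiment()` draws loci *without*
replacement at each requested size, 100 times by default, and compares each
size's distribution against the full panel's estimate and CI and against
any supplied reference — the design that separates locus count from
missingness. Every replicate has its own derived seed (`seed + b`, redraw
attempt $t$ shifting by $tB$; size $s$, draw $r$ using
`seed + (s-1)reps + r`), so any replicate is reproducible in isolation.
Replicates with an undefined statistic are redrawn, capped at $10B$, never
silently dropped — replicate counts stay exact. Because every multilocus
statistic is a ratio of per-locus sums, replicates are computed from the
per-locus component table; this is algebraically identical to recomputing
from genotypes.

## Genotype PCA

`pca_genotypes()` uses the standard dosage pipeline: alternate-allele
counts, mean imputation of missing cells, centering by $2\hat p$, optional
$\sqrt{\hat p(1-\hat p)}$ scaling (the default; `none` is exposed because
normalisation conventions differ between tools and the choice is recorded
in the result). Mean imputation is the conservative choice for a
visualisation PCA: an individual with no data lands exactly at the origin
rather than at an extrapolated position. Multiallelic loci are dropped
with a warning by default or one-hot expanded to per-allele dosages
(`multiallelic = "expand"`) for SSR panels.

## Numerical and design choices

* Rounding of percent-required values is half-up (`floor(x*10 + 0.5)/10`),
  not banker's rounding.
* Histogram bins are half-open $[lo, lo+w)$ with a small epsilon guard so
  values like 1.0 at width 0.05 land in the bin their arithmetic says.
* Undefined statistics are `NA` plus a flag, at every level.
* A locus with zero calls is dropped by any completeness cutoff $\ge 1$;
  a fully missing locus has undefined MAF and is removed by the MAF filter.
* genepop allele code 0 is a missing allele; a half-missing call is treated
  as fully missing, as is a half-called VCF genotype (`./1`).
* Problem sizes in the test suite: L = 5000 for estimator recovery,
  L = 1000 with 20 replicates for the dropout contrast, 100 seeded runs of
  L = 1000 for CI coverage, L = 2000 two-deme panels for PCA separation —
  sizes at which Monte-Carlo noise is well below the asserted tolerances.

## Limitations

* The gene-diversity $F_{ST}$'s finite-$K$ offset means its bootstrap CI is
  an interval for the among-sample differentiation, not the generating $F$;
  use `"theta"` when the target is the model parameter.
* With 8 individuals per deme, per-deme frequency estimates are noisy;
  per-locus statistics at loose cutoffs are dominated by sampling noise —
  that is part of the phenomenon under study, not an artefact to remove.
* The dropout model treats null alleles as locus-independent; real
  restriction-site mutations can be shared across nearby tags.
* `run_full_experiment()` holds each family member in memory; panels far
  beyond ~10^5 loci would need chunked processing.
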