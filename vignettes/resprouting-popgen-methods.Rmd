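---
title: "Methods: microsatellite differentiation, outlier scans, clustering and demographic scenario choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsatellite differentiation, outlier scans, clustering and demographic scenario choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`msatpop` implements a complete population-genetic workflow for codominant
microsatellite data from two phenotypically divergent population groups —
the motivating system is a fire-adapted shrub/tree with northern
lignotuberous (basal-resprouting) and southern epicormic
(stem-resprouting) populations. This vignette documents the statistical
models, the numerical choices, and the limits of what the package's tests
demonstrate.

## Data model

A `genotype_dataset` stores, for each diploid individual and locus, an
unordered pair of allele states (positive integers on whatever length scale
the genotyping produced — repeat units or nucleotides; the package never
rescales them). A call is either complete or missing; half-missing calls
are promoted to missing on input. Population labels partition individuals;
an optional mapping assigns each population to a phenotype group.
Statistics always average over *defined* loci: a (population, locus) with
no data propagates as undefined rather than zero, so missingness cannot
bias a mean toward zero.

## Diversity and differentiation statistics

Per population we report the mean number of alleles per locus ($A$), the
effective number $A_E = 1/\sum_i p_i^2$, observed heterozygosity ($H_O$),
and unbiased expected heterozygosity with Nei's small-sample correction,
$H_E = \frac{2n}{2n-1}\left(1 - \sum_i p_i^2\right)$. Because $A$ is highly
sample-size dependent, `diversity_table()` can first standardize every
population to a common number of individuals (`standardize_sample()`,
seeded subsampling without replacement; rarefaction is deliberately not
implemented — subsampling keeps every downstream statistic computable from
one concrete dataset).

Differentiation uses the Nei–Chesser bias-corrected heterozygosities,

$$\hat H_S = \frac{2\tilde n}{2\tilde n - 1}\Big(1 - \overline{\sum_i p_i^2}\Big),
\qquad
\hat H_T = \Big(1 - \sum_i \bar p_i^2\Big) + \frac{\hat H_S}{2\tilde n k},$$

with $\tilde n$ the harmonic mean of the per-population diploid sample
sizes and $k$ the number of populations. From these come:

* **GST** (the multi-allelic FST): $\sum_\ell(\hat H_T - \hat H_S) / \sum_\ell \hat H_T$,
  loci aggregated by summing numerators and denominators;
* **Hedrick's standardized F'ST**, the ratio of GST to its maximum
  attainable value given $\hat H_S$, via the closed form
  $G'_{ST} = G_{ST}\,(k - 1 + \hat H_S)\,/\,[(k-1)(1 - \hat H_S)]$.
  High-diversity markers compress GST (its ceiling is roughly $1 - H_S$);
  the standardization undoes that compression so values are comparable
  across marker sets;
* **Jost's D** per locus, $\frac{k}{k-1}\,\frac{\hat H_T - \hat H_S}{1 - \hat H_S}$,
  with the multi-locus summary an arithmetic mean over defined loci
  (a harmonic-mean variant is available; since the group contrasts are
  reported per locus, the choice of aggregate is cosmetic).

Negative estimates are legitimate finite-sample outcomes and are stored as
computed, never clamped. Significance uses label permutations of
individuals between the two populations of a pair,
$p = (1 + \#\{perm \ge obs\})/(1 + n_{perm})$, with Bonferroni correction
across pairs; per-locus bootstrap bounds resample individuals with
replacement within populations (percentile 2.5/97.5% bounds by default,
replicate range available — both interpretations of "bootstrap bounds" seen
in published figures). Group-level contrasts (`locus_differentiation()`)
compute a statistic within group 1, within group 2, and *between* groups
with the two groups pooled into two units ($k = 2$); pooling is appropriate
here because within-group differentiation is near zero.

## FST-outlier scan

`three_set_scan()` re-implements the FDIST approach: simulate the joint
null distribution of (heterozygosity, FST) for neutral loci under a
symmetric island model whose migration rate is tuned to the observed
multi-locus FST, slice the simulated cloud into twenty equal-occupancy
heterozygosity bins, record the empirical 0.5%, 50% and 99.5% FST
quantiles per bin, and interpolate piecewise-linearly between bin
midpoints. A locus outside the interpolated 99% band at its own
heterozygosity is an outlier; loci beyond the simulated heterozygosity
range are classified against the nearest bin and flagged as extrapolated.

Null model choices (all configurable): 100 islands, of which the sampled
populations occupy as many as were genotyped, with the observed diploid
sample sizes; stepwise mutation (microsatellite-appropriate;
infinite-alleles and generalized-stepwise variants available); per-locus
scaled mutation rates drawn log-uniformly from 0.2–30 so the cloud spans
the heterozygosity axis. The analytic migration inversion
$M = (1/F_{ST} - 1)\,((d-1)/d)^2$ ignores mutation, which biases realized
FST slightly low at high diversity, so by default a 1,000-locus pilot cloud
re-tunes $M$ multiplicatively — after which the realized cloud mean lands
on the target to well under 0.01. A cloud of 20,000 loci keeps the 99.5%
quantile curves smooth; very small target FST values (< 0.001) are
simulated as panmixia.

The scan runs three times — all populations, each phenotype group alone —
each against its own null (trimmed once: outliers found in the first pass
are removed from the target-FST estimate and the scan re-run). The
decision rule reports loci that are outliers in the whole set but in
neither group alone: differentiation tied to the group contrast rather
than to structure inside a group. By default only *high*-side outliers
enter this rule (elevated differentiation is the signature of divergent
selection, which is what the phenotype association targets); low-side
outliers remain visible in the per-locus status tables and can be included
with `side = "both"`.

## Admixture clustering and choice of K

`fit_admixture()` is a minimal Gibbs sampler for the admixture model of
model-based clustering: each allele copy carries a latent cluster
assignment drawn given the individual's admixture proportions $Q_i$ and
the cluster allele frequencies $P_k$; $P_k$ gets conjugate
Dirichlet($\lambda$ + counts) updates and $Q_i$ Dirichlet($\alpha$ +
counts) updates. Deliberate simplifications relative to the full
STRUCTURE model: $\alpha$ is fixed at 1 (no hyperparameter updating), no
correlated-frequencies model, no linkage model, no prior population
information. For strongly structured data (the regime of interest here,
between-group F'ST ≈ 0.27) these refinements do not change the inferred
number of clusters, and the simple sampler mixes quickly. The model
evidence is estimated as $\widehat{\ln P(X|K)} = \overline{\ln L} -
\mathrm{var}(\ln L)/2$ from the post-burn-in trace, and the number of
clusters is chosen by the Evanno second-difference statistic
$\Delta K = |\bar L(K{+}1) - 2\bar L(K) + \bar L(K{-}1)| / sd(L(K))$ over
replicate runs (undefined at the endpoints of the scanned range; an
infinite value with a warning when runs are bit-identical). Note an
inherent property of the admixture posterior: with $2L$ allele copies per
individual, the posterior mean membership of even a perfectly assigned
individual is about $(\alpha + 2L)/(2\alpha + 2L)$ — with 11 loci, ~0.96 —
so "crisp" assignment thresholds must respect the number of loci.

Default chain lengths are 5,000 burn-in + 50,000 sweeps. The inference
target here (K = 2 on strongly separated groups) is insensitive to much
shorter chains; the package's own K-selection checks use 500 + 3,000
sweeps with three runs per K over K = 1–4, which reproduces the same
$\Delta K$ peak in seconds.

## ABC over divergence scenarios

Three demographic scenarios relate the two phenotype groups (pop1 =
lignotuberous, pop2 = epicormic): (1) pop1 ancestral and pop2 derived
through a founder bottleneck at the divergence time $t_1$; (2) the mirror
image; (3) both derived from an unsampled ancestor, each through its own
bottleneck. Priors: effective sizes uniform 10,000–100,000; bottleneck
size $N_b$ uniform 10–100 lasting $d_b \sim$ uniform 250–750 years (1–3
generations at a 250-year generation time); $t_1 \sim$ normal(25,000,
5,000) years truncated to $t_1 > d_b$ (the bottleneck must fit inside the
derived lineage — a structural necessity); per-locus mutation rate uniform
$10^{-4}$–$10^{-3}$; generalized-stepwise geometric parameter uniform
0.1–0.3 and single-nucleotide-indel rate log-uniform $10^{-8}$–$10^{-5}$
(standard defaults for microsatellite ABC where the study itself states
none). Scenario 3's two bottlenecks share the single ($N_b$, $d_b$) draw,
keeping one parameter vector per record. Years convert to generations by
division and rounding (minimum 1).

The coalescent simulator tracks lineages backward through the
piecewise-constant population sizes, merges at $t_1$, and drops mutations
on branches: geometric step sizes on a 40-state motif ladder with
reflecting bounds, plus indels that shift fragment length by one
nucleotide off the 3-nt motif ladder. Reported allele states are fragment
lengths in nucleotides; observed data supplied to `summary_stats()` should
be on a consistent length scale. Summary statistics (12): per population
the means over loci of allele number, unbiased expected heterozygosity,
allele-size variance and Garza–Williamson $M = A/(\text{range}+1)$
(bottleneck-sensitive); pairwise FST, Jost's D, mean shared-allele
distance, and $(\delta\mu)^2$. These are the classic microsatellite ABC
summaries; the bottleneck asymmetry between scenarios 1 and 2 is carried
mostly by the per-population allele number and $M$.

Scenario choice standardizes statistics by table-wide median absolute
deviation (constant columns drop out), ranks records by Euclidean
distance, and reports scenario proportions among the accepted records
(direct estimate) and fitted multinomial-logistic probabilities at
difference zero over a larger neighborhood (ridge-stabilized via weight
decay 0.01, so separable neighborhoods remain estimable; a single-scenario
neighborhood falls back to the direct estimate). Parameter posteriors are
weighted quantiles (Epanechnikov weights in distance) of accepted draws
under the chosen scenario, with optional local-linear regression
adjustment. Confidence is evaluated by reclassifying reference records as
pseudo-observed datasets and tabulating the confusion matrix.

Reference-table sizing: the package default for exploratory runs is
3 × 20,000 records at the observed sample sizes (builds in about a minute
at 11 loci and 25 diploids per population); acceptance counts default to
1,500 (direct) and 15,000 (logistic) when the table is at least that
large, and `run_all()` scales them as the fixed fractions 1,500/6e6 and
15,000/6e6 when a configured table is smaller, preserving the acceptance
rate rather than the absolute count.

## The synthetic study emulator

No genotype matrix is published for the motivating study, so
`generate_two_cluster_dataset()` manufactures data with the study's
statistical signature: 6 + 8 populations in two groups, 25–35 diploids
each, 11 loci with a ~198-allele total budget, between-group mean F'ST on
target (default 0.27) with near-zero within-group differentiation.
Frequencies follow a two-level Balding–Nichols-style model — ancestral
Dirichlet(0.3) per locus, group-level Dirichlet drift, population-level
Dirichlet drift (0.005) — and genotypes are drawn under
Hardy–Weinberg. The between-group drift is calibrated by bisection on the
*realized* between-group mean F'ST of the generated dataset. All
randomness is pre-drawn and pushed through quantile transforms, so a
realization is a continuous, deterministic function of the drift
parameter and the bisection converges cleanly; the calibrated value must
land within ±0.03 of the target or generation errors out.
`inject_outlier_locus()` then replaces one locus (named C112 in the
default fixture) with draws from group-specific frequency vectors: one
allele at frequency 0.87 in the epicormic group, all 17 alleles below 0.20
in the lignotuberous group, the same allele support in both — the
signature of a selection-associated marker that is differentiated between
resprouting types but unremarkable within each.

What the emulator does *not* reproduce: linkage, null alleles, genotyping
error, isolation-by-distance within groups, departures from HWE, and
mutation-model realism (population frequencies are drawn, not evolved).
Tests passing on this fixture demonstrate that the estimators, decision
rules and samplers behave as designed under the study's statistical
regime — not that the original field data would yield identical numbers.

## Numerical and reproducibility choices

Every stochastic entry point takes an explicit integer seed, runs in a
private RNG stream, and restores the caller's RNG state; reference tables
derive per-chunk seeds so builds are reproducible and chunk-parallelizable.
Degenerate inputs follow one rule: undefined propagates (monomorphic loci
drop out of FST aggregates and Jost's D; a globally monomorphic dataset
returns `NA` flagged, and a permutation test on an undefined statistic
returns p = 1). Ties sit on the "neutral" side of envelope classification.
Problem sizes used by the package's own checks — 20,000-locus null clouds,
3 × 20,000-record reference tables, 50 pseudo-observed replicates,
3,000-sweep chains — were chosen as the smallest sizes at which the
quantities being checked are stable to well within their test tolerances.

## Known limitations

* GenoDive/STRUCTURE/FDIST2/DIYABC numeric identity is not claimed; the
  methods, not the executables, are re-implemented, and estimator variants
  differ in detail (e.g. F'ST via Hedrick's closed form rather than
  maximal allele recoding).
* The admixture sampler's label identity is resolved only post hoc
  (greedy matching of clusters to reference labels); nothing aligns
  clusters across independent runs.
* The island-model null conditions on a single target FST; hierarchical
  structure (e.g. groups within the whole set) is handled by running the
  scan per set, not by a hierarchical island model.
* ABC results are as good as the summary statistics: with 11 loci the
  scenario-1-vs-2 contrast rests on modest asymmetries in allele number
  and Garza–Williamson M, and weakly informative datasets yield posterior
  probabilities near 1/3 — the confidence evaluation quantifies exactly
  this.
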