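---
title: "Simulating genetic risk prediction studies: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating genetic risk prediction studies: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genrisksim)
```

## The problem

Empirical genetic risk prediction studies genotype a cohort, build a risk
score from a SNP panel, and report the area under the ROC curve (AUC).
`genrisksim` asks how much of that result was already determined by the
panel's summary statistics: given only per-allele odds ratios (ORs),
risk-allele frequencies and an average population disease risk, it
constructs a hypothetical cohort whose re-estimated parameters match those
inputs and measures the AUC a risk model would achieve on it. When that
expected AUC is low, an empirical study is arguably premature.

## The generative model

Each SNP is parameterized by a risk-allele frequency $p$ and a per-allele
odds ratio $OR$ (both reoriented so the tabulated allele is the risk
allele). Genotype frequencies follow Hardy–Weinberg equilibrium,
$(g_0, g_1, g_2) = ((1-p)^2,\, 2p(1-p),\, p^2)$, and disease odds are
multiplicative in the allele count: genotype $i$ has odds $o_0\,OR^i$. The
baseline $o_0$ is fixed by the constraint that the average genotype risk
equals the population disease risk $d$:
$$\sum_{i=0}^2 g_i\,\frac{o_0\,OR^i}{1 + o_0\,OR^i} = d.$$
From the solved genotype risks $p_i$ the genotype likelihood ratios are
$LR_i = p_i(1-d)\,/\,(d(1-p_i))$, which satisfy $LR_i/LR_0 = OR^i$ exactly
and average to 1 over the control genotype distribution.

A cohort of $N$ individuals is then built in three steps: (1) genotypes are
independent Hardy–Weinberg draws per SNP, with SNPs mutually independent
(linkage equilibrium); (2) each individual's disease risk comes from Bayes'
theorem with independent SNP effects (naive Bayes),
$\text{odds} = \tfrac{d}{1-d}\prod_g LR_{g i_g}$ and
$\text{risk} = \text{odds}/(1+\text{odds})$; (3) disease status is 1 when
the risk exceeds an independent uniform(0,1) draw.

Three risk models are scored on a cohort: the **unweighted** count of risk
alleles, the **weighted** score $\sum_g c_g \ln OR_g$ ($c_g$ = allele
count), and the **bayes** posterior risk. Published logistic-regression
studies are replicated with the bayes score: under linkage equilibrium the
jointly fitted weights converge to the generating marginal log odds, the
posterior odds are monotone in the weighted score, and AUC is
rank-invariant, so the three routes order individuals identically (the
package tests assert the bayes/weighted AUC equality to 1e-12, and
`refit_logistic_auc()` provides the in-sample refit as an explicit
cross-check).

AUC is estimated nonparametrically as the Mann–Whitney probability that a
random patient outscores a random nonpatient, computed from midrank sums in
$O(n\log n)$ with ties counted half — ties matter for integer allele-count
scores, where whole percentage points of AUC can sit in tied pairs.

## Parameters and defaults

* **`d` (population disease risk)** — a proportion; the Bayes prior.
  Shipped constants for the six diseases covered by the benchmark
  (`disease_risks()`): type 2 diabetes 0.20, prostate cancer 0.15, type 1
  diabetes 0.002, age-related macular degeneration 0.065, colorectal cancer
  0.048, Crohn disease 0.002. These are lifetime/period risks from the
  epidemiological literature the replicated studies drew on.
* **`n_sim`** — cohort size, default 100,000: large enough that Monte-Carlo
  noise in a single-cohort AUC is ±0.002–0.003, small enough that one
  iteration takes a fraction of a second.
* **`n_iter`** — replication iterations, default 100; reported AUCs are
  means over iterations, stabilizing the estimate to ±0.0005 or so.
* **`or_strategy`** — `"point"` uses published ORs throughout;
  `"ci_sampled"` redraws each SNP's log OR once per iteration from a normal
  distribution whose SD is implied by the published 95% CI
  (`log_or_sd_from_ci()`).

## The packaged panels

Two 18-SNP type 2 diabetes panels ship with the package
(`t2d_godarts.tsv`, `t2d_rotterdam.tsv`), encoding the per-allele ORs from
the GWASs cited by two prediction studies of the same risk model; they
differ only at the three SNPs (KCNJ11, TCF2, TCF7L2) whose cited GWAS
differs between the studies. The `raf` column carries approximate
European-ancestry control frequencies compiled from the same GWAS
literature — synthetic stand-ins for the exact control frequencies those
GWASs tabulated, flagged as such in the files. The
acceptance checks that both panels replicate to a mean bayes AUC of 0.61
(and the 18-SNP unweighted score to 0.60) therefore ride on frequencies
chosen once from the literature, not fitted.

The 29-row `replication_benchmark()` table pairs each published study's AUC
with the simulation estimate for it, grouped by risk-model type; it is the
input to `compare_to_published()` and the deterministic part of the
acceptance suite.

## Numerical choices

* **Root finding.** The prevalence equation is strictly increasing in
  $o_0$, so the root is unique; it is located by bisection on
  $\ln o_0 \in [-40, 40]$, stopping when the prevalence is matched to
  1e-12 (at most 200 halvings). Bisection is immune to the flat tails the
  logistic curve develops at extreme odds.
* **Risk-allele reorientation.** A row with $OR < 1$ is replaced by
  $(1-p,\ 1/OR,\ 1/\text{ci}_\text{high},\ 1/\text{ci}_\text{low})$ — the
  unique conversion consistent with a biallelic 2×2 table. The rule is an
  involution, and resampled ORs falling below 1 are reoriented the same way
  rather than truncated, preserving the sampling distribution.
* **CI resampling scale.** "Drawn from the 95% CI assuming normality" is
  scale-ambiguous; the package draws on the log-OR scale, the standard
  sampling model for odds ratios, which keeps draws positive and treats
  Woolf-symmetric intervals exactly. The point-vs-CI insensitivity check
  (mean AUCs within 0.01) shows the choice is immaterial here.
* **Rounding in comparisons.** Published AUCs are printed at 2 decimals, so
  all comparison arithmetic happens on 2-decimal values; medians of
  even-sized groups use the midpoint and are reported rounded half-away-
  from-zero (base `round()` rounds half to even, which would misreport
  0.015).
* **Degenerate inputs.** Zero cells in a 2×2 table, absent CIs under the
  CI-sampling strategy, constant scores in the quintile split, cohorts with
  no cases or no controls, and constant risks in the scatter's $R^2$ all
  raise immediate errors naming the offending cell/SNP; the package never
  applies a silent continuity correction.
* **Quintile cut points** default to the 20/40/60/80 percentiles of the
  simulated score distribution, with `(lo, hi]` binning so values equal to
  a cut point fall below it; external (published) thresholds can be
  injected. Integer scores with few distinct values can tie adjacent
  percentiles — that surfaces as an empty-cell error rather than a silent
  merge. $R^2$ in the scatter is the squared Pearson correlation between
  allele count and posterior risk (conventions differ across studies; this
  one is recorded in the output metadata).
* **Seeding.** All randomness flows through R's global generator, seeded
  explicitly per cohort; iteration $k$ of a replication uses
  `base_seed + k`, and under CI sampling the OR redraw and the cohort draw
  share that iteration's stream. Identical study, strategy and seed
  reproduce results bit for bit.

## What re-estimation recovers — and a deliberate deviation

Because genotype odds are multiplicative by construction, re-estimating a
SNP's OR from the simulated data recovers the input without bias when done
on the genotype scale (heterozygote-vs-reference 2×2 table, or logistic
regression on allele count). The *allele-count* 2×2 table — alleles rather
than people — additionally assumes Hardy–Weinberg proportions within cases,
which fails slightly at appreciable prevalence: at $d = 0.2$ the allelic
log OR is attenuated by roughly 1–2.5% for $OR \ge 1.4$. At
$n = 100{,}000$ a Woolf 95% CI is only about ±2% wide, so an
allele-table coverage test would reject the construction for strong SNPs
even though the generating model is exactly as specified. The acceptance
suite therefore asserts Woolf-CI coverage (≥93% over 100 seeded replicates)
on the unbiased heterozygote-vs-reference estimate and bounds the
allele-table bias explicitly (mean log-OR discrepancy below 0.03). For
GWAS-scale ORs (≤1.5) at lower prevalence the distinction is invisible.

## What the generator emulates — and what it does not

The simulator reproduces the epidemiological skeleton of a prediction
study: allele frequencies, marginal per-allele effects, prevalence, and the
resulting score distributions. It deliberately omits linkage
disequilibrium, non-multiplicative (dominant/recessive/interaction)
effects, covariates and secular risk factors, genotyping error and missing
data, and case-control ascertainment artifacts. Passing tests therefore
show that the machinery is faithful to the stated model, not that real
cohorts obey it; empirical AUCs can differ because real ORs are adjusted,
correlated, or winner's-curse-inflated relative to the GWAS values fed in.
The benchmark's accuracy summaries (median absolute AUC differences of
0.02–0.05 depending on model type) are the package's own measure of how far
that idealization lands from published reality.

## Problem sizes in the test suite

The acceptance checks run the full protocol — 100 iterations of 100,000
individuals for the two 18-SNP panels, 100 seeded cohorts of 100,000 for
parameter recovery and oracle equivalence (3–5 SNP panels, where the
$3^G$ enumeration oracle `analytic_auc()` is exact), and 20 iterations for
the null-panel checks. Unit tests use cohorts of 2,000–50,000 individuals;
the brute-force $O(n^2)$ AUC oracle is exercised at $n \le 200$. The whole
suite completes in a few minutes on one CPU.

## Limitations

Beyond the modelling omissions above: the package replicates discrimination
only (no calibration, reclassification or AUC confidence intervals, which
the replicated studies did not consistently report); weighted-score
replications use the same ORs for generation and weighting, so their model
fit is optimistic relative to an empirical study whose literature weights
mismatch its own data; and published AUCs from small studies are themselves
noisy, so a residual median difference of a few hundredths is expected even
under a perfect generative model.
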