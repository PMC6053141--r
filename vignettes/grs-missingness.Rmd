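---
title: "Methods: simulating GRS performance under SNP missingness"
author: "grsmiss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating GRS performance under SNP missingness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsmiss)
```

## The problem

A genetic risk score (GRS) is a per-person sum of risk-allele counts over a
set of SNPs, optionally weighted by each SNP's log odds ratio from a
discovery study. When the score is carried to a new target sample, some of
its SNPs are often unavailable — different genotyping arrays, low call
rates, or weights taken from the literature. For a score built from a
*small* number of SNPs (tens, not thousands), the two cheap remedies are

* **omission** — compute the score from the available SNPs only, and
* **proxy replacement** — substitute, for each unavailable SNP, an
  available SNP in linkage disequilibrium (LD) with it, chosen from a
  reference panel of matching ancestry. Proxy quality is graded by the
  squared Pearson correlation $r^2$ between the two SNPs' allele counts in
  the reference panel: excellent ($r^2 \ge 0.9$), very good
  ($0.8 \le r^2 < 0.9$), good ($0.6 \le r^2 < 0.8$).

This package measures what either remedy costs, by simulation, in four
currencies: the odds ratio per standard deviation (OR/SD) of the score, the
statistical power to detect the score–phenotype association, the area under
the ROC curve (AUC), and the Pearson correlation between the estimated
score and the complete **gold standard** score.

## The causal model

Phenotypes are generated from the score itself. With $X_{ij} \in \{0,1,2\}$
the risk-allele count of person $j$ at causal SNP $i$,

$$\operatorname{logit} P(Y_j = 1 \mid X_j) = \mu + \sum_{i=1}^{50} \beta_i X_{ij},$$

where $\beta_i$ is the per-allele log odds ratio of SNP $i$. Two weight
designs are studied:

* **common** (`make_common_weights()`): all $\beta_i = \log(\text{OR})$
  with a per-allele OR between 1.05 and 1.10. The model then depends on the
  genotypes only through the total risk-allele count, which is exactly the
  unweighted GRS.
* **heavy-tailed** (`make_tada_like_weights()`): 50 ORs emulating a
  published coronary-heart-disease score from its summary statistics —
  three fixed extreme ORs (1.51, 1.45, 1.29) at random positions plus 47
  ORs drawn from a symmetric triangular distribution centred at 1.07.

The triangular spread is set so the *interquartile range of the ORs is
0.04*. The source description of the emulated score prints an IQR of 0.4,
but also states that the three extreme ORs sit more than 1.5 IQR above the
third quartile — arithmetically impossible with IQR 0.4 (the fence would
exceed 1.6). Reading the IQR as 0.04 makes the outlier rule hold, and the
suite asserts it on every draw. Any distribution matching the median and
IQR would do; the triangular one is used because it is bounded (all ORs
stay above 1) and trivial to sample.

The intercept $\mu$ fixes the disease risk of a person with no risk
alleles, $\operatorname{expit}(\mu)$. It is calibrated **once per weight
scheme** (`calibrate_mu()`) so the marginal phenotype frequency is 50%: a
calibration sample of 200,000 genotype rows is drawn — in chunks of 400
rows, each chunk with a fresh MAF vector, mirroring the study design where
every simulated dataset has fresh allele frequencies — and $\mu$ is found
by bisection of the mean predicted risk on that fixed sample. Bisection on
a fixed Monte Carlo sample is deterministic and monotone; the Monte Carlo
error of the achieved prevalence is about 0.001, well inside the 0.005
acceptance tolerance. Phenotypes are then Bernoulli draws with
$p_j = \operatorname{expit}(\mu + \sum_i \beta_i X_{ij})$.

## The synthetic genotype panel

`build_panel()` emulates the genotype resource the study design assumes: a
target sample of 404 individuals and an independent reference panel of 99
(a CEU-like panel; its size is a package choice, as reference panels of
about a hundred individuals are typical), with 50 causal SNPs — five per
each of ten LD blocks, mutually independent — and, for every causal SNP,
three proxy SNPs realizing the three $r^2$ tiers.

* **MAF spectrum.** Causal MAFs are Uniform(0.05, 0.5): the 5% floor is
  the usual quality filter, and this spectrum reproduces the implied
  standard deviation of the gold-standard unweighted score
  ($\sqrt{50 \cdot E[2p(1-p)]} \approx 4.27$ allele counts), which is what
  links the per-allele OR to the reported OR/SD range 1.23–1.50. It is a
  calibrated surrogate, not an empirical spectrum.
* **HWE by construction.** Each SNP is generated as two independent
  Bernoulli haplotypes per individual (random mating), so genotype
  frequencies are Hardy–Weinberg; `hwe_chisq()` verifies calibration.
* **LD machinery.** A proxy shares its causal SNP's allele frequency
  (high-LD pairs tend to share frequencies, and equal frequencies make
  every $r \in [0,1]$ feasible) and is drawn haplotype-wise conditional on
  the causal haplotypes at correlation $r = \sqrt{r^2_\text{tier}}$, via
  the two-locus haplotype frequencies of `make_ld_haplotype_freqs()`.
  Under random mating the genotype-count correlation equals the haplotype
  correlation, which the suite checks against an enumeration oracle.
* **Rejection on the reference panel.** The tier definition applies to the
  *reference-panel* $r^2$, so each proxy is redrawn until its realized
  reference $r^2$ lands inside its tier bin (targets are the bin midpoints
  0.95, 0.85, 0.70). If a causal SNP's reference column cannot support all
  three tiers within the retry budget — which happens for unlucky low-MAF
  draws, where 99 reference genotypes make $r^2$ too grainy — the causal
  SNP itself is redrawn with a fresh MAF. This mirrors the study design's
  restriction of the SNP pool to SNPs with all three proxy qualities
  available, at the price of slightly disfavouring the lowest MAFs.

What the generator deliberately does **not** emulate: real chromosomal LD
structure beyond index–proxy pairs, population substratification, missing
genotype calls within a SNP, or MAF spectra estimated from sequence data.
Passing tests therefore demonstrate the behaviour of the missingness
strategies under idealized HWE genotypes with exactly realized proxy
tiers, not under any particular cohort's LD patterns.

## Scores, masks and strategies

Each iteration draws a fresh mask (`draw_missing_mask()`) marking exactly
20%, 30%, 50% or 70% of the 50 causal SNPs (10/15/25/35 — fixed counts,
not binomial thinning) as unavailable; redrawing the mask every iteration
is what gives the correlation distributions their spread. Five scores per
person are computed by one weighted-sum code path (`grs_set()`):

* gold standard — all 50 SNPs;
* omission — available SNPs only;
* three proxy scores — available SNPs plus, for each masked SNP, its
  oriented proxy of the given tier.

The unweighted GRS uses unit weights (a pure allele count); the weighted
GRS uses the causal betas. Proxy *orientation* is decided on the reference
panel alone — the target-sample causal SNP is unavailable by assumption —
and a negatively correlated proxy enters as $2 - \text{count}$.

## Evaluation

Per iteration and score: a univariate logistic regression of the phenotype
on the SD-standardized score gives the OR/SD and a two-sided Wald p-value
(`fit_or_per_sd()`); the AUC is the midrank Mann–Whitney estimator with
the half-tie convention, needed for integer-valued unweighted scores
(`auc_rank()`); and the Pearson correlation with the gold standard is
recorded. Standardization uses the per-dataset sample SD — "per SD" is
read as within-dataset. Fits with failed IRLS convergence or
quasi-complete separation (fitted probabilities within 1e-8 of 0/1, or
|slope| > 10) are flagged, excluded from aggregation and counted; at the
design's effect sizes they are far below 1% of iterations.

Scenario cells are summarized (`summarize_results()`) by the 5th/25th/
50th/75th/95th percentiles of the OR, power as the share of p < 0.05 (no
multiplicity correction, by design), the median AUC and correlation
percentiles, optionally stratified by the number of available
extreme-weight SNPs or by mean-MAF bins.

For a single standardized predictor under the equal-variance binormal
model, the AUC is a closed form of the log OR per SD:
$\text{AUC} = \Phi(\beta_\sigma / \sqrt{2})$ (`closed_form_auc()`). The
printed form of this relation in the source material is typographically
garbled; the package adopts the standard result, and the simulations agree
with it to well under 0.01 in every scenario cell, which is the check the
acceptance suite runs. Since the score is standardized, $\sigma = 1$ and
the log OR per SD enters directly.

## Determinism and problem sizes

All randomness in a study derives from `sim_config()$seed`: iteration $k$
re-seeds R's generator with a value derived from (base seed, $k$), so any
iteration is reproducible in isolation, and re-running a study reproduces
its tables byte for byte. Iteration 0 is reserved for the weight-scheme
draw and intercept calibration.

The default `n_iterations` is 10,000, the full study size. The package's
own verification runs use 2,000 iterations per scenario — at the study's
sample size (n = 404) this puts the Monte Carlo standard error of a
scenario median OR near 0.003, an order of magnitude below the effects
being measured — and the test suite's smoke tests use single digits.
Panels are regenerated every iteration; the study this emulates held one
real genotype panel fixed, so regeneration widens the Monte Carlo spread
slightly but introduces no bias, and it is the honest synthetic analogue.

## Known limitations

* The emulated heavy-tailed weights match the published score's summary
  statistics, not its exact OR vector, so weighted-design results carry
  that extra emulation error (the gold-standard weighted median OR/SD
  lands within a few percent of the reported 1.63).
* One proxy per missing SNP; no multi-proxy combinations, no dosage
  imputation, no person-level sporadic missingness.
* Phenotypes are generated and analysed with the same weights — weights
  are treated as known, isolating the missingness effect from weight
  estimation error.
* The binormal closed form is an approximation whose quality degrades for
  very large effects; within the design's OR range it is accurate to a
  few thousandths of AUC.
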