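---
title: "Multi-locus QTL mapping across NAM families: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-locus QTL mapping across NAM families: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nammap)
```

## The problem

A nested association mapping (NAM) population crosses k diverse founder
lines to a single common parent and selfs each cross into a family of
recombinant inbred lines (RILs). Mapping all families jointly multiplies
the sample size and the allelic diversity, but a locus need not carry the
same effect in every family: founders differ, and the same SNP can be
strongly associated in one family, weakly in another, and not at all in a
third (genetic heterogeneity). A joint model that forces one effect per
SNP averages these away; a fully family-specific model

$$ y = \lambda\mu + \sum_{i=1}^{q}\sum_{j=1}^{k} X_{ij}\beta_{ij} + \varepsilon $$

(with \(\lambda\) the n × k family-indicator block, \(X_{ij}\) the ±1
genotype of SNP i restricted to family j, zero elsewhere) is honest but
has k·m effect columns for m SNPs — far too many to fit jointly when m is
in the thousands.

`nammap` implements a dimension-reduction transform that keeps the
family-specific information while using **one** column per SNP, fits all
columns jointly with an empirical-Bayes (E-Bayes) shrinkage EM, and
validates the surviving effects with likelihood-ratio tests.

## The recoding transform

For SNP i, each line falls into one of 2k (family, genotype) classes. Let
\(\omega_{j,g} = \bar y_{j,g} - \bar y\) be the phenotype deviation of
class (j, g) from the grand mean (`omega_profile()`). Sorting the classes
by \(\omega\) and assigning each class a code that is a monotone function
of that order produces a single incidence vector \(Z_i\)
(`recode_snp()`); the transformed model is

$$ y = \lambda\mu + \sum_{i=1}^{q} Z_i\gamma_i + \varepsilon . $$

A single coefficient \(\gamma_i\) now carries the SNP's signal in all
families, because the per-family allele contrast is encoded in the class
codes. Per-family additive effects are recovered afterwards as
\(\hat\beta_{ij} = \hat\gamma_i\,(c_{j,aa} - c_{j,AA})/2\)
(`backtransform_effects()`).

Three code choices are provided:

* `"omega"` (default): the class code **is** its \(\omega\) deviation.
  The column then carries both the order and the spacing of the class
  means, and the back-transformed per-family effects agree with
  family-wise OLS (this is checked against an OLS oracle in the test
  suite).
* `"rank"`: integer ranks 1..(#classes). Order-faithful, but it forces
  equally spaced codes onto classes whose means may be nearly tied; in
  particular, when all families share the same effect the rank column does
  *not* collapse exactly onto the plain ±1 coding (two families' AA
  classes get distinct ranks), and back-transformed effect spacing is
  distorted. Detection power is indistinguishable from `"omega"` in our
  simulations; effect estimation is why it is not the default.
* `"segmented"`: adjacent sorted classes whose \(\omega\) gap is below
  0.1 × sd(y) share one code. The 0.1 factor is scale-free; tied classes
  always merge. This reproduces the collapse to the ±1 coding when
  families genuinely agree.

Columns are centered and scaled to unit variance; the fit is invariant to
this, but it keeps the EM well conditioned. A column with no
within-family code variation (a SNP monomorphic in every family, or all
\(\omega\) tied) is collinear with \(\lambda\) and is flagged degenerate
and excluded from estimation, keeping its index.

Because \(\omega\) is computed from the phenotype, the transform is a
one-pass, data-dependent recoding: it is computed once on the full data
set and never resampled. Class-mean noise at small per-QTL heritability
is the main price of the dimension reduction — with ~100 lines per class
the ordering of weak-effect classes is itself noisy, which is what
ultimately limits power for 3%-variance QTLs.

## Empirical-Bayes shrinkage EM

All m columns enter jointly with normal priors
\(\gamma_k \sim N(0, \sigma_k^2)\) and scaled inverse-\(\chi^2\)
hyperpriors \(\sigma_k^2 \sim \mathrm{Inv}\text{-}\chi^2(\tau, \omega)\)
with \(\tau = \omega = 0\) (an improper prior under which the variance
update divides by 3). With
\(V = \sum_k Z_k Z_k^\top \sigma_k^2 + I\sigma^2\):

* E-step: \(E(\gamma_k) = \sigma_k^2 Z_k^\top V^{-1}(y - X\beta)\),
  \(\mathrm{var}(\gamma_k) = \sigma_k^2 - \sigma_k^4 Z_k^\top V^{-1} Z_k\).
* M-step: \(\sigma_k^2 = [E(\gamma_k^\top\gamma_k) + \omega]/(\tau + 3)\),
  then \(\beta\) by GLS and
  \(\sigma^2 = (y - X\beta)^\top[y - X\beta - \sum_k Z_k E(\gamma_k)]/n\).

This shrinkage is deliberately aggressive: null columns decay
geometrically to zero while strongly supported columns are left nearly
unshrunk. Numerical choices:

* **Initialisation.** \(\beta\) by OLS, \(\sigma^2\) from its residuals,
  \(\gamma_k = 0\), \(\sigma_k^2\) = squared marginal OLS slope of each
  column, floored at \(10^{-6}\mathrm{Var}(y)\). A data-adaptive start
  converges in a few dozen iterations; experiments with a flat, larger
  start changed nothing but the iteration count.
* **Pruning floor.** A column whose \(\sigma_k^2\) falls below
  \(10^{-8}\mathrm{Var}(y)\) is set to exactly zero and permanently
  dropped from V. This keeps the Woodbury inner matrix small and well
  conditioned. We also evaluated the alternative of keeping all columns
  in V so that the later t-ratio screen does the winnowing: the screened
  set then contains dozens of near-null, mutually correlated columns,
  the ML refit becomes strongly collinear, and detection power *drops*
  (46% → 33% at per-QTL h² = 0.03 in our simulations). The floor stays.
* **Convergence.** Maximum absolute change across
  \((\beta, \sigma^2, \sigma_k^2)\) below \(10^{-6}\), at most 200
  iterations; typical fits converge in 25–75.
* **Linear algebra.** All \(V^{-1}\) products use the Woodbury identity
  in the space of active columns (`marginal_solve()`), so the per-iteration
  cost scales with the active-column count, not n². The Woodbury and
  dense paths agree to \(10^{-8}\) (tested).

## Two-stage selection

Columns with \(|\hat\gamma_k|/\hat\sigma_k > 10^{-4}\) are screened in
(`screen_snps()`; permissive by design — with the pruning floor this
mostly ratifies the active set). The screened reduced model is refit by
maximum likelihood (plain multiple regression, `ml_refit()`), and each
column j is tested by
\(LR_j = -2\ln[L(\hat\theta_{-j})/L(\hat\theta)]\), reported as
\(LOD = LR_j/4.61\) and retained when \(LOD \ge 3\) (`lrt_each()`).

Two readings of \(\hat\theta_{-j}\) are implemented. The default,
`lr_method = "drop"`, takes \(\hat\theta_{-j}\) to be \(\hat\theta\) with
the tested effect removed and every other parameter — coefficients and
residual variance — held at its joint estimate; since the full-model
residuals are orthogonal to column j this evaluates to
\(LR_j = \hat\gamma_j^2\lVert Z_j\rVert^2/\hat\sigma^2\). The
alternative, `lr_method = "refit"`, re-maximises the reduced model (the
textbook nested LRT). The distinction matters under LD: the nested refit
lets correlated neighbouring columns absorb the dropped column's signal,
which in our simulations costs roughly 11–13 points of average power at
per-QTL h² of 3–5% while leaving the false positive rate essentially
unchanged; the drop form reproduces the detection behaviour this method
is known for, and is the default. Either way, because removing one
column changes the others' tests, the refit + test cycle is repeated
until the retained set is stable (at most 10 rounds, `select_qtl()`); in
practice it stabilises in 1–3 rounds. Per-QTL variance explained is
reported as the squared correlation between the column's fitted
contribution and y.

A consequence of a fixed per-marker threshold worth stating plainly: at
LOD 3 (per-marker p ≈ 2×10⁻⁴) a 100-marker null genome still produces at
least one false call in a sizeable minority of replicates (the
per-marker false-call rate is ~0.6%, comfortably below the ~2% level the
method is expected to stay under, but a genome-wise "no calls at all"
guarantee would need a stiffer, multiplicity-adjusted threshold).

## The simulator

`simulate_nam()` generates the study conditions used throughout:

* **Genotypes.** Each RIL chromosome is a two-state ±1 Markov chain along
  the map with switch probability \(R = 2r/(1+2r)\), r from Haldane's map
  function (no interference) — the classical expansion of recombination in
  selfed RILs. The default map is 100 evenly spaced markers over
  153.4 cM (≈1.55 cM spacing, matching the density of the maize NAM
  chromosome-1 subset this emulates), with 10 QTLs on evenly spaced
  markers (every 10th, ≈15.5 cM apart). Simulated genotypes stand in for
  the real marker data, which cannot be redistributed here; real-data LD
  is locally irregular in ways a uniform map is not.
* **Fixed-effect scenarios.** Per-QTL heritability h² (share of total
  phenotypic variance) sets the target additive variance
  \(\sigma_{ai}^2 = h_i^2\sigma_e^2/(1-\sum h^2)\) with
  \(\sigma_e^2 = 1\). The k family effects of each QTL are an equally
  spaced, zero-sum pattern (for k = 5 proportional to (−2,−1,0,1,2)),
  independently permuted across families per QTL, rescaled so that the
  family-average squared effect equals \(\sigma_{ai}^2\) (genotype
  variance is 1). The spread pattern maximises between-family
  heterogeneity — the regime the method targets; the zero-sum constraint
  holds to machine precision.
* **Random-effect scenario.** QTLs 1–5 carry a common effect 1.5 in all
  families; QTLs 6–10 draw their k effects from
  \(\mathrm{MVN}(1.5\cdot\mathbf 1, \Sigma)\),
  \(\Sigma_{ab} = \rho^{|a-b|}\). The residual variance is set so the
  total heritability is 0.6 — computed from the **analytic** additive
  variance \(\sum_i \overline{\alpha_{i\cdot}^2}\), not from the realised
  variance of breeding values. The distinction matters: with all effects
  near +1.5 and adjacent QTLs only ~15 cM apart, positive LD
  cross-covariances inflate the realised genetic variance well above the
  per-QTL sum; calibrating on the realised value would silently raise the
  noise by ~60% and is inconsistent with the per-QTL variance accounting
  used in the fixed-effect scenarios. The same analytic convention is
  used in both places.

What the simulator does **not** emulate: real founder haplotype structure
and family-specific allele frequencies, missing or erroneous genotypes,
segregation distortion, non-uniform marker spacing, epistasis. Passing
the simulation studies therefore demonstrates the statistical machinery
under idealised RIL linkage, not performance on any particular real
population.

## Evaluation

`match_calls()` assigns each call to the nearest true QTL within a 5 cM
window, at most one call per QTL (nearest wins; further calls at the same
QTL count as false positives). 5 cM is small enough to separate the
≈15.5 cM-spaced QTLs and large enough to absorb the 1–3 cM position
noise observed at these heritabilities. The false positive rate divides
unmatched calls by the number of non-QTL markers. Power per QTL is the
fraction of replicates detecting it; effect bias compares
back-transformed per-family effects of a matched call with the true
effects of its QTL (signed mean and absolute mean). With zero true
positives the biases are reported as `NA`, never as zero.

## Problem sizes used by the checks

The packaged test suite exercises the full simulation studies at 25
Monte-Carlo replicates per scenario cell (null-data suite: 100
replicates), which bounds the whole suite to a few minutes; the
acceptance script (`scripts/acceptance.R`) runs the same studies at 100
replicates per cell. Replicate seeds are drawn once from the master seed,
so every study is reproducible end to end.

## Known limitations

* Power at small per-QTL heritability is limited by class-mean noise in
  the transform (above): with ~100 lines per genotype class the ordering
  of weak-effect classes is itself noisy, and no amount of downstream
  modelling recovers what the recoding blurs.
* A null genome is not guaranteed to produce zero calls; the LOD 3.0
  threshold controls the per-marker, not the genome-wise, false-call
  rate (see the selection section).
* The ω-based recoding uses the phenotype; its codes are mildly
  overfit at very small class sizes. Families with an empty genotype
  class at a SNP get `NA` back-transformed effects (not estimable).
* The LRT threshold is fixed at LOD 3.0; no permutation calibration is
  provided.
* Heterozygotes, outbred designs and VCF/PLINK input are out of scope;
  genotypes are strictly ±1 with missing values mean-imputed per family.
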