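---
title: "Reconstructing association models from naive summary statistics"
author: "oathr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing association models from naive summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A genome-wide association study (GWAS) is usually published under one
model — a particular choice of nuisance covariates, most often the top
eigenvectors of the genetic relationship matrix (GRM) used to absorb
population stratification. Readers who would like to re-examine a hit
under a different covariate combination normally need the
individual-level data, which data-sharing constraints often put out of
reach. The central observation implemented here is that ordinary least
squares only ever touches the data through second moments: the sample
size $n$ together with the variance–covariance entries of phenotype,
genotype and covariates are *sufficient statistics* for every linear
association model that can be formed from those variables. We call this
minimal set the **naive summary statistics** (NSS).

## The estimator

For locus $i$, collect the covariances of $[y, x_i, z_1, \dots, z_m]$
(phenotype, allele count, covariates) into the symmetric
$(m+2)\times(m+2)$ matrix $\Phi_i$. For any covariate subset $s$ of size
$k$, let $\Omega$ be $\Phi_i$ restricted to the predictors
$[x_i, z_s]$, $\Lambda = \mathrm{diag}(\Omega)$, and
$\hat b_j = \mathrm{cov}(y, v_j)/\mathrm{var}(v_j)$ the *marginal*
(single-predictor) coefficients. Then the multiple-regression
coefficients are

$$\hat\beta = \Omega^{-1} \Lambda \hat b,$$

with sampling covariance

$$\widehat{\mathrm{var}}(\hat\beta)
  = \frac{\sigma^2_y - \hat\beta^\top \Lambda \hat b}{\nu}\,\Omega^{-1},$$

where $\nu$ is the residual degrees of freedom. Because every entry of
$\Phi_i$ carries the same $n-1$ denominator, the estimator is invariant
to the covariance denominator; the package uses $n-1$ throughout and
only requires that one NSS set be internally consistent. `oath_fit()`
implements this with a Cholesky factorization of $\Omega$ (reused for
the covariance diagonal; a pivoted solve is the fallback at the PSD
boundary), a reciprocal-condition-number guard of $10^{-12}$ against
collinear covariate subsets, and $p$-values computed in log space from
the $t$ survival function so extreme signals never underflow to zero.

Only the row of $\Phi_i$ involving the genotype changes from locus to
locus. The NSS exchange format therefore splits into a *generic* block
(`.gnss`, JSON: $n$ plus the covariance matrix of phenotype and
covariates) shared genome-wide, and one *locus* row per SNP (`.lnss`,
TSV: alleles, frequency, call rate, genotype variance and the
genotype–phenotype/covariate covariances). Both files are plain text,
diff-able and lossless to about $10^{-9}$ relative at `%.10g`.

## Degrees of freedom

With the variables centered, the residual degrees of freedom of the
subset-$k$ model are written $\nu = n - k - 1$; a with-intercept least
squares program reports $\nu = n - k - 2$. The two differ by a factor
$\sqrt{(n-k-1)/(n-k-2)}$ in the standard errors — negligible at
realistic $n$, but the package must pick one to be exactly
reproducible. The default `df_convention = "centered"` uses $n-k-1$, the
literal centered-variable form; `"ols"` matches `lm()` exactly and is
what the test suite's individual-level oracle uses.

## Variables that are not pre-centered

Inputs are not centered in storage; all covariances are computed about
sample means, which is algebraically identical to centering every
variable first. Missing genotypes are mean-imputed per locus *after*
recording the call rate and observed-call allele frequency, so that one
shared $n$ serves the generic block and every locus (the estimator
assumes a single $n$ per $\Phi_i$). Rows missing the phenotype or any
covariate are dropped globally before anything is encoded, with a
logged count. Mean imputation shrinks the genotype variance slightly at
low call rates; the default call-rate filter (0.998) keeps that effect
below reporting precision.

## Marker quality control

`qc_filter()` removes non-biallelic records, minor allele frequency
below 0.05, call rate below 0.998 and — when enabled — homozygote
fraction below 0.99. All comparisons are strict (`<`), so a locus
sitting exactly on a threshold is kept, and each removal carries its
first failing reason in the fixed order non-biallelic, maf, callrate,
homozygosity. The homozygosity screen targets inbred-line panels
(selfing species where residual heterozygosity indicates genotyping
problems) and is off by default for outbred data. It needs the
homozygote fraction, which the exchange format does not carry, so it
applies at encode time where hard calls are available.

## Scanning, enumeration and hit calling

`oath_scan()` fits every locus under one covariate subset; loci that
cannot be fitted (monomorphic, collinear) are carried with a flag and a
reason rather than dropped, so record counts are stable. The
genomic-control inflation factor is
$\lambda_{GC} = \mathrm{median}(t^2)/q_{\chi^2_1}(0.5)$, using the
squared SNP $t$ statistics as 1-df statistics (at scan-scale residual
degrees of freedom the $t^2$-vs-$\chi^2_1$ gap is below reporting
precision). `gc_adjust()` deflates each statistic to $t^2/\lambda_{GC}$
and recomputes the $p$-value from the $\chi^2_1$ tail, but only when
$\lambda_{GC} > 1$: genomic control is a correction for inflation, and
deflation-only application is the standard practice; a well-calibrated
or deflated scan is left untouched.

`enumerate_models()` fits all $2^m$ covariate subsets of a locus
($2^m - 1$ when the covariate-free model is excluded), guarded at
$m \le 20$; `enumerate_scan()` streams this across loci. A locus is an
*any-model hit* when at least one subset exceeds the Bonferroni
threshold $-\log_{10}(\alpha / \text{\#tests})$, and hit calling is
strict (`>`), so a value exactly at the threshold does not qualify. The
threshold is always computed directly from $\alpha$ and the
multiplicities — the package never hard-codes a printed threshold.

For the in-depth evaluation of a hit, the $2^m$ $-\log_{10}(p)$ values
are sorted and split into groups wherever two neighbours differ by
*more than* one unit (a gap of exactly one stays in-group — the strict
reading keeps group counts stable when inputs are rounded; the gap is a
parameter). Group separation is then quantified by the one-way ANOVA
$F$ across groups. With zero within-group variance the $F$ is reported
as `Inf` with the $-\log_{10} p$ capped at 300 (beyond double-precision
underflow); a single group or zero total variance is reported as not
applicable (`NA`) rather than 0, because "no separation measurable" is
not "no separation".

## Meta-analysis

Each cohort encodes its own NSS once — with its own covariates,
typically the top eigenvectors of its own GRM — and ships the two text
files to the hub. The hub intersects SNP ids, aligns alleles to the
first cohort (an exact pair match passes; a swapped pair flips the sign
of the genotype covariances and the frequency; anything else is
excluded as an allele mismatch — strand flips are never guessed, and
palindromic A/T and C/G variants are aligned by labels only with a
warning), fits the chosen covariate subset per cohort, and pools by
inverse-variance fixed effects:
$w_i = 1/\mathrm{se}_i^2$, $\hat\beta = \sum w_i \hat\beta_i / \sum w_i$,
$\mathrm{se} = (\sum w_i)^{-1/2}$, with the pooled $z$ referred to the
standard normal (cohort degrees of freedom are large and unequal, so a
common $t$ reference would be arbitrary). No heterogeneity model is
fitted. Because the full NSS are at the hub, switching the covariate
subset requires no re-export from the cohorts — the practical payoff of
the design.

## What the simulators emulate — and what they do not

`sim_genotypes()` draws independent loci with ancestral frequencies
uniform on `maf_range` and, under structure, subpopulation frequencies
from the Balding–Nichols model
$\mathrm{Beta}(p(1-F_{st})/F_{st},\,(1-p)(1-F_{st})/F_{st})$ — the
standard minimal model that makes eigenvector covariates meaningful.
Inbred mode doubles a haploid draw, so every call is homozygous, as in
selfing-species panels. `grm()` standardizes each locus by $2\hat p$
and $\sqrt{2\hat p(1-\hat p)}$; `top_eigenvectors()` fixes each
eigenvector's sign by making its largest-magnitude entry positive, for
bit-reproducibility. `sim_phenotype()` builds
$y = \sum_c \sqrt{h^2_c}\, w_c + Zb + e$ from empirically standardized
causal genotypes, so each causal locus's marginal variance share
matches its specification up to sampling error.

Two packaged designs fix the study conditions end to end:

* `sim_gwas()` — an inbred panel of 295 lines, 2,000 loci, three
  subpopulations at $F_{st} = 0.05$, five GRM-eigenvector covariates,
  two causal loci at 2% variance each.
* `sim_two_cohorts()` — cohorts of 3,191 and 2,309 samples sharing
  9,124 loci drawn from common ancestral frequencies, mild
  two-subpopulation structure ($F_{st} = 0.01$), one shared causal
  locus at 5% variance, three eigenvector covariates per cohort. The
  phenotype model beyond the causal share (Gaussian noise, no covariate
  effects) is this package's choice.

The simulators deliberately omit linkage disequilibrium, genotyping
error, relatedness beyond subpopulation structure, and non-additive
architecture. Tests passing on these designs therefore demonstrate the
*algebraic* claim — that summary-statistic reconstruction equals
individual-level least squares — and the qualitative behaviour of
$\lambda_{GC}$ under stratification; they do not certify behaviour on
real panels with LD or cryptic relatedness, where the linear model
itself (not the reconstruction) is the limitation.

## Numerical choices, in one place

* Covariance denominator $n-1$ everywhere; the estimator is invariant
  to the choice but consistency is enforced.
* Symmetry tolerance $10^{-12}$ relative; positive-semi-definiteness
  tolerance $10^{-8}$ relative on the smallest eigenvalue;
  Cauchy–Schwarz consistency between generic and locus blocks with a
  $10^{-9}$ slack.
* Collinearity guard: reciprocal condition number $> 10^{-12}$ on
  $\Omega$; genuine collinearity errors name the subset.
* A negative computed residual variance (numerically possible with
  inconsistent or rounded inputs) is clamped at zero and the fit is
  flagged degenerate, never reported as a small negative variance.
* $p$-values from the $t$ distribution (finite-sample least squares),
  on the log scale; the genomic-control-adjusted ones from
  $\chi^2_1$.
* Eigenvector sign convention: largest-magnitude entry positive.
* All generators take explicit seeds and restore the caller's RNG
  state.

## Problem sizes used by the checks

The packaged verification runs use the study-design sizes where they
are stated (two cohorts of 3,191 and 2,309 with 9,124 loci for the
meta-analysis demonstration; a 295-sample panel for the reconstruction
comparison) and desk-scale sizes elsewhere (a 2,000-locus panel for the
genome-wide fidelity correlation; 3,000–5,000 null loci for
$\lambda_{GC}$ calibration; 100 random datasets crossed with all
covariate subsets for the oracle-equivalence property). The
reconstruction-vs-oracle comparisons are exact to $10^{-8}$ relative
under the matching degrees-of-freedom convention; the printed worked
example is checked at display-rounding tolerance ($2\times10^{-3}$),
since its published $\Phi$ is itself rounded.

## Known limitations

Linear models only: linear mixed models, generalized linear models and
interaction terms are out of scope — the sufficient-statistic algebra
above is specific to least squares. Allele alignment is exact-match
only (no strand inference). The meta-analysis is fixed-effects only; no
$Q$/$I^2$ heterogeneity statistics are reported. X-chromosome dosage
conventions and imputation to a reference panel are not handled.
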