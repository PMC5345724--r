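# oathr

Reconstruction of genome-wide association study (GWAS) results — effect
estimates, standard errors and p-values, for **any** subset of
covariates — from *naive summary statistics* (NSS): the sample size plus
the variance–covariance entries of phenotype, genotype and covariates.

It is aimed at analysts who want to re-examine published associations
without access to individual-level data, and at consortia that want a
central hub to be able to switch GWAS models (e.g. which ancestry
eigenvectors to adjust for) without asking every cohort to re-run and
re-export anything.

## The idea

Ordinary least squares touches the data only through second moments.
Collect the covariances of `[y, x_i, z_1..z_m]` (phenotype, allele
count at locus *i*, covariates) into the symmetric matrix Φᵢ. For any
covariate subset *s* of size *k*, with Ω the predictor block of Φᵢ,
Λ = diag(Ω) and b̂ the marginal single-predictor coefficients,

```
β̂ = Ω⁻¹ Λ b̂,        var(β̂) = (σ²_y − β̂ᵀ Λ b̂) / (n − k − 1) · Ω⁻¹
```

reproduces the multiple-regression fit exactly — no individual-level
data needed. Only the genotype row of Φᵢ changes per locus, so a whole
scan ships as one small generic block (`.gnss`) plus one text row per
SNP (`.lnss`). On top of the estimator the package provides genome-wide
scans with genomic-control λ, exhaustive enumeration of all 2^m
covariate-subset models with Bonferroni "any-model" hit calling and an
in-depth evaluation (p-value grouping + one-way F), inverse-variance
fixed-effects meta-analysis of per-cohort NSS with allele alignment,
marker QC, PLINK/dosage/VCF input, and seeded simulators (structured
genotypes, GRM, eigenvector covariates, additive phenotypes).

## Worked example

The single-locus demonstration fixture (a biallelic locus with MAF
0.23, zero true effect, three standard-normal covariates, n = 200)
ships as `worked_example_phi()`:

```r
library(oathr)
phi <- worked_example_phi()
oath_fit(phi, s = c(1, 2, 3))     # saturated model, all three covariates
```

```
OATH fit, subset { 1,2,3 }, df = 196
 term     beta      se      t
    x  0.01382 0.12130  0.114
   z1  0.09469 0.07044  1.344
   z2 -0.12780 0.07025 -1.819
   z3  0.11000 0.07045  1.561
SNP -log10(p) = 0.04127 (sigma2_resid = 0.9635)
```

The SNP term (`x`) is null, as designed; dropping all covariates
(`s = integer(0)`) gives the marginal fit with β = −0.0148 — the ratio
of the fixture's printed covariance −0.005 to its genotype variance
0.338. Any of the 2^3 = 8 covariate combinations can be fitted from the
same matrix.

A consortium-style run, entirely from simulated NSS (two cohorts, a
shared causal locus at 5% variance, each cohort adjusted by its own GRM
eigenvectors):

```r
tc  <- sim_two_cohorts(seed = 7, n1 = 400, n2 = 300, n_loci = 500,
                       causal_h2 = 0.05, n_covariates = 3)
res <- meta_scan(tc$cohorts, s = c(1, 3))   # adjust eigenvectors 1 and 3
head(res$table[order(-res$table$mlog10p), ], 3)
```

```
 snp_id n_cohorts beta_meta se_meta    z mlog10p
  1_364         2     0.269  0.0534 5.03    6.32
  1_361         2     0.179  0.0520 3.44    3.24
  1_500         2     0.229  0.0745 3.07    2.68
```

`1_364` is the planted causal locus; its pooled −log10(p) = 6.32 clears
the 500-locus Bonferroni threshold of 4.00. Re-running `meta_scan()`
with any other covariate subset uses the same cohort files — nothing is
re-exported.

## Command line

A thin launcher over the same functions ships in `inst/exec/oath`:

```sh
oath encode  --dosage geno.tsv --pheno pheno.tsv --covar covar.tsv --out study
oath scan    --nss study --subset "+-+--" --out study        # Table-style masks or "1,3"
oath enumerate --nss study --out study                       # all 2^m models per locus
oath meta    --nss cohortA,cohortB --subset all --out pooled
oath simulate --n 295 --loci 2000 --covariates 5 --seed 1 --out sim
```

Exit codes: 0 success, 2 usage/contract error, 3 data error.

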