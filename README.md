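# dimorphQTL

`dimorphQTL` is an R package for studying **sex dimorphism in the genetic
regulation of gene expression** and its downstream consequences on complex
traits. It is aimed at statistical geneticists who want to test, end to end
and on data with known ground truth, the hypothesis chain

> sex-biased *cis*-eQTL → causal effect of expression on a trait →
> sex-biased GWAS association,

and to quantify how large a GWAS would have to be before such mediated sex
differences become detectable.

## What it computes

* **Sex-stratified cis-eQTL mapping** — Spearman rank correlation between
  dosage and expression for every SNP–gene pair within an inclusive ±1 Mb
  window around the SNP, per sex stratum, with principal-component
  correction that retains any component associated with genotype, and a
  sample-size-weighted fixed-effect meta-analysis of the strata.
* **Sex-difference statistics** — for standardized eQTL effects
  (variance convention var(β̂) = 1/N):

      t = (β_F − β_M) / √(1/N_F + 1/N_M)

  and for GWAS effects with explicit standard errors:

      t = (β_F − β_M) / √(SE_F² + SE_M²)

  plus expression mean (t on standard errors of the mean) and variance
  (F = σ²_F/σ²_M) dimorphism tests, Benjamini–Hochberg FDR selection,
  lead-eQTL choice, hypergeometric set enrichment, Wilcoxon rank-sum and
  Levene checks, and an eigenvalue-based effective number of independent
  tests for Bonferroni denominators.
* **Transcriptome-wide Mendelian randomization (TWMR)** — multivariable
  inverse-variance-weighted MR from summary statistics,

      α̂ = (Eᵀ C⁻¹ E)⁻¹ Eᵀ C⁻¹ G,

  run per sex on genes with ≥ 3 independent significant (P < 10⁻³) eQTL
  instruments, with delta-method standard errors and a z-contrast of the
  female and male causal effects.
* **Analytic power / sample size** — under full mediation
  β_GWAS(s) = α · β_eQTL(s), the sex-difference statistic is normal with
  noncentrality

      ncp = α (β_eQTL(F) − β_eQTL(M)) / √(1/N_GWAS(F) + 1/N_GWAS(M)),

  giving power ≈ 2(1 − Φ(5.43 − |ncp|)) and a closed-form-bracketed
  search for the total sample size reaching a target power.
* **A synthetic-data generator** — Hardy–Weinberg genotypes, per-sex
  standardized eQTL effects of equal sign and different magnitude, per-sex
  expression noise, and traits generated under the mediation model — the
  ground truth against which every statistical property is verified.

Genotypes and expression live in `GenotypeExperiment` /
`ExpressionExperiment` containers (thin `SummarizedExperiment` extensions
with 1-based genomic positions in `rowRanges`); summary statistics travel
as plain data frames in a stable TSV layout (`readSummaryStats()` /
`writeSummaryStats()`), and genotypes can also be read from VCF.
All coordinates are 1-based inclusive, sex labels are the literal strings
`"F"`/`"M"`, and missing genotypes are `NA` (dropped pairwise).

## Worked example

Simulate a cohort of 1500 women and 1500 men with 6 genes × 5 cis SNPs in
which half of the SNP–gene pairs are sex-biased (β_F = 0.4 vs β_M = 0.15),
run the whole pipeline, and inspect the result:

```r
library(dimorphQTL)

rep <- runPipeline(list(
  sim = list(nF = 1500, nM = 1500, nGenes = 6, nSnpsPerGene = 5,
             betaF = 0.4, betaM = 0.15, fracSexBiased = 0.5,
             alphaF = 0.15, alphaM = 0.15),
  seed = 11))
rep
#> Sex-dimorphism pipeline run (seed 11 )
#>   pairs tested: 30; significant at FDR 0.05: 22 (p <= 0.0193)
#>   sex-biased eGenes: 6 (lead eQTLs: 6)
#>   TWMR genes F/M: 6/6; contrast-significant: 0

head(rep$tables$lead_eqtls[, c("snp_id", "unit_id", "beta_F", "beta_M",
                               "statistic", "p_diff", "q")])
#>      snp_id unit_id beta_F beta_M statistic   p_diff        q
#> 5  g001_s05    g001  0.306 0.1136      5.27 1.36e-07 8.14e-07
#> 10 g002_s05    g002  0.302 0.1385      4.48 7.59e-06 2.07e-05
#> 12 g003_s02    g003  0.364 0.1399      6.12 9.07e-10 2.72e-08
#> 19 g004_s04    g004  0.302 0.1335      4.60 4.20e-06 1.57e-05
#> 21 g005_s01    g005  0.292 0.0948      5.39 7.08e-08 5.31e-07
#> 26 g006_s01    g006  0.316 0.1022      5.86 4.66e-09 6.99e-08
```

Of 30 cis pairs, 22 show a significant female–male difference at FDR 5%
(the realized p-threshold 0.0193 is reported alongside), clustering in 6
eGenes; each lead row carries the per-sex rank-correlation effects, the
difference statistic and its BH q-value. The truth table
(`rep$truth$eqtl`) confirms every flagged gene carries a genuinely biased
pair.

How detectable would such an eQTL difference be in a sex-stratified GWAS
of 190,000 women and 170,000 men, if expression causally moves the trait
by α = 0.15 per standardized unit?

```r
powerSexDiff(0.15, 0.4, 0.15, 190000, 170000)
#>        ncp power
#> 1 11.23263     1

requiredSampleSize(0.15, 0.4, 0.15)
#> [1] 76226
```

An extreme effect gap like 0.25 would be detectable (power 1, needing
~76 k samples) — but for realistic gaps an order of magnitude smaller the
same calculation demands millions of participants, which is the central
quantitative message of the power module
(`requiredSampleSize(0.2, 0.05, 0)` ≈ 1.07 million).

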