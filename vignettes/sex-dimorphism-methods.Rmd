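---
title: "Models and methods behind dimorphQTL"
author: "dimorphQTL authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dimorphQTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimorphQTL)
```

# The scientific question

Many complex traits differ between the sexes, and a natural molecular
explanation would be sex-biased genetic regulation of gene expression:
a *cis*-eQTL whose standardized effect on a gene is stronger in one sex
could propagate, through a causal effect of that gene on a trait, into a
sex-biased GWAS association. `dimorphQTL` implements the full analysis
chain needed to investigate this hypothesis on data where the truth is
known: sex-stratified *cis*-eQTL mapping, z/t statistics for sex
differences in eQTL and GWAS effects, expression mean/variance
dimorphism tests, transcriptome-wide Mendelian randomization (TWMR) per
sex with a contrast on the causal effect, and an analytic power model
for the mediated sex difference.

Real consortium data of this kind (whole-blood eQTL cohorts, biobank
GWAS) are access-controlled, so the package ships a synthetic-data
generator that emulates the statistical structure those analyses assume
and serves as ground truth for every test in the suite.

# Sex-stratified cis-eQTL mapping

A SNP–gene pair is *cis* when the gene's center position lies within
1 Mb of the SNP (both directions, boundary inclusive — the window rule
is symmetric around the SNP, and inclusivity removes an off-by-one
ambiguity at exactly 1 Mb). Within each sex stratum the association is
the Spearman rank correlation $\hat\beta = \rho_s$ over the stratum's
complete cases (average ranks on ties), with the two-sided p-value from
$t = \rho_s \sqrt{(n-2)/(1-\rho_s^2)}$ on $n-2$ degrees of freedom.
Rank correlation makes the mapping invariant to any strictly monotone
transformation of expression and robust to the Gaussian noise assumption
of the generator.

Standardized effects of this kind have large-sample variance $1/n$. We
use $1/n$ rather than Fisher's $1/(n-3)$ because it is the denominator
of the downstream sex-difference statistic
$t = (\beta_F - \beta_M)/\sqrt{1/N_F + 1/N_M}$, keeping the chain
internally consistent; at the sample sizes involved the difference is
negligible. The fixed-effect meta-analysis of the strata follows the
same convention:
$\beta_c = (N_F\beta_F + N_M\beta_M)/(N_F+N_M)$, $z = \beta_c\sqrt{N_F+N_M}$.

## Principal-component correction

Expression is optionally residualized on its leading principal
components to remove unmeasured global variation (batch, cell-type
composition) without erasing genetic signal: each of the first `nPcs`
(default 25) components is screened against every SNP by simple
regression, and any component with a minimum association p-value below
`assocPThreshold` (default `1e-12`, a deliberately extreme cutoff so
only unambiguously genetic components are withheld) is *not* regressed
out. Whether components should be computed per stratum or on the
combined sample is genuinely open; we compute them once on the combined
sample, which is how large eQTL consortia operate, and the residuals are
recomputed identically for both strata so the sex contrast is not
distorted by stratum-specific rotations.

# Sex-difference statistics

All contrasts are z-style large-sample statistics with standard-normal
p-values:

* eQTL effects: $t = (\beta_F-\beta_M)/\sqrt{1/N_F+1/N_M}$ (standardized
  effects, variance $1/n$);
* GWAS effects: $t = (\beta_F-\beta_M)/\sqrt{SE_F^2+SE_M^2}$ (explicit
  standard errors);
* expression means: the same form with standard errors of the mean;
* expression variances: $F = \sigma^2_F/\sigma^2_M$ against an
  F distribution. We use the statistically standard degrees of freedom
  $(N_F-1,\,N_M-1)$; a `dfAsPrinted` toggle reproduces the
  $(N_F,\,N_M)$ convention some reports print, which changes p-values
  only in the third decimal at cohort-scale $n$. Sidedness is the
  doubled smaller tail, capped at 1.

Multiplicity is handled the way the two scans require: the genome-wide
eQTL-difference scan uses Benjamini–Hochberg step-up FDR (reported with
the realized p-value threshold, the largest selected p), while the
phenome-screen of lead eQTLs against many traits uses Bonferroni with an
*effective* number of phenotypes in the denominator,
$0.05/(m_{\mathrm{eff}} \times n_{\mathrm{eGenes}})$. The effective
count is the eigenvalue-based (Li–Ji-style) estimate
$m_{\mathrm{eff}} = \sum_j \left[\mathbf{1}(\lambda_j\ge 1) +
(\lambda_j-\lfloor\lambda_j\rfloor)\right]$ of the phenotype correlation
matrix — never a hard-coded constant. BH was chosen over Storey's
q-value because the scan's p-value distribution is overwhelmingly null;
the FDR level stays configurable.

A lead eQTL per gene is the record with maximal $|t|$; ties break by
smaller p, then lexicographically smallest SNP identifier, so the choice
is deterministic.

# Transcriptome-wide Mendelian randomization

Instruments for a focal gene are its significant eQTLs
($p < 10^{-3}$ by default), greedily pruned to pairwise $r^2 < 0.1$
keeping the smallest p first ("independent" instruments; the cutoff is
configurable because the field does not quantify it uniformly). A gene
enters the analysis only with at least 3 surviving instruments. Every
other gene co-instrumented by a retained SNP joins as an additional
exposure column, giving the multivariable design that absorbs local
pleiotropy.

The estimator is multivariable inverse-variance-weighted MR from summary
statistics with LD weighting:

$$\hat\alpha = (E^\top C^{-1}E)^{-1}E^\top C^{-1}G,$$

which with identity $C$ and one exposure reduces to the familiar ratio
estimator $\sum_i E_i G_i / \sum_i E_i^2$. The default standard error is
the first-order delta-method propagation of both summary inputs,

$$\widehat{\mathrm{var}}(\hat\alpha) =
\mathrm{diag}\!\left[(E^\top C^{-1}E)^{-1}\right]
\left(\frac{1}{N_{\mathrm{GWAS}}} +
\frac{\sum_q \hat\alpha_q^2}{N_{\mathrm{eQTL}}}\right),$$

in which the eQTL-noise term is scaled by the causal effects because a
perturbation $\delta E$ moves $\hat\alpha$ only through $\delta E\,
\alpha$. The cruder inflation form with $1/N_{\mathrm{eQTL}}$ unscaled
is available as `seMethod = "inflation"`; it upper-bounds the delta
form whenever $|\alpha| < 1$ and makes confidence intervals
conservative by the factor
$\sqrt{(1/N_G + 1/N_E)/(1/N_G + \alpha^2/N_E)}$ (about four-fold at
$\alpha = 0.1$ with $N_E = 3000$, $N_G = 50000$). The delta form is the
default because parameter-recovery simulations show it reproduces the
empirical sampling spread and gives ~95% interval coverage, which the
inflation form cannot.

The sex contrast on causal effects is the same z-difference used for
GWAS effects, $t = (\alpha_F-\alpha_M)/\sqrt{se_F^2+se_M^2}$ — chosen
over an interaction model for consistency with the other contrasts —
with a Bonferroni threshold over the genes contrasted.

# The analytic power model

Under full mediation, the sex-specific GWAS effects are
$\beta_{\mathrm{GWAS}(s)} = \alpha \, \beta_{\mathrm{eQTL}(s)}$ with a
shared causal effect $\alpha$, so the GWAS difference statistic is
normal with unit variance and mean

$$\mathrm{ncp} = \frac{\alpha\,(\beta_{\mathrm{eQTL}(F)} -
\beta_{\mathrm{eQTL}(M)})}{\sqrt{1/N_{\mathrm{GWAS}(F)} +
1/N_{\mathrm{GWAS}(M)}}}.$$

The default power is the upper-tail approximation
$2(1-\Phi(c - |\mathrm{ncp}|))$ with $c = 5.43$, clipped to $[0,1]$; an
exact two-sided mode adds the opposite tail instead of doubling.
Numerical care points:

* the formulas are evaluated at $|\mathrm{ncp}|$ so power is symmetric
  in the sign of the mediated difference and strictly increasing in its
  magnitude;
* the approximation equals the exact power at $\mathrm{ncp}=0$ (both
  give the nominal size $2(1-\Phi(c)) \approx 5.6\times10^{-8}$),
  bounds it from above, and at most doubles it — the two are close only
  where power is tiny, which is exactly the regime the model is used in;
* the critical constant: the conventional printed value is 5.43, while
  recomputing the upper $2.5\times10^{-8}$ normal quantile gives
  $\Phi^{-1}(1-2.5\times10^{-8}) = 5.4513$. Both are supported
  (`critValue(recompute = TRUE)`); required sample sizes differ by
  under 1% across the default grid, so no conclusion depends on the
  choice, and neither constant is asserted as ground truth.

`requiredSampleSize()` inverts the monotone power curve by bracketing
the closed-form inversion
$N = \left[(c - \Phi^{-1}(1-\gamma/2))/(\alpha\,\Delta\beta)\right]^2
/ (r(1-r))$ and bisecting over even totals, so both strata stay
integral at the default female fraction $r = 0.5$ (which a grid scan
confirms is the minimizing allocation). `powerGrid()` tabulates power
and required totals over user-supplied effect grids; the causal-effect
quantiles behind published power surfaces are not printed anywhere, so
grids are always explicit arguments.

# What the generator emulates — and what it does not

`simParams()` fixes a scenario: Hardy–Weinberg genotypes with MAF drawn
uniformly from `mafRange` (default 0.05–0.5), loci 3 Mb apart (at most
80 per synthetic chromosome, keeping coordinates in the integer range),
each gene's SNPs within ±0.9 Mb of its center; per-sex standardized
eQTL effects of the same sign (a configurable fraction of pairs is
sex-biased, females taking `betaF`, males `betaM` — defaults 0.4/0.2, a
gap in the middle of the plausible 0.05–0.4 range, which real data do
not pin down); Gaussian expression noise with per-sex standard
deviations; and a trait
$y = \sum_g \alpha_{s,g}\,\mathrm{expr}_g + \sum_j \delta_j\,
\tilde x_j + \varepsilon$, $\varepsilon\sim N(0,1)$, where
$\delta = 0$ gives full mediation. Default cohort sizes are 1928 women
and 1519 men, the scale of a large whole-blood eQTL study. Dosages are
standardized by the estimated allele frequency,
$(x - 2\hat p)/\sqrt{2\hat p(1-\hat p)}$, before effect injection so
that injected effects sit on the standardized scale on which the
$1/n$ variance convention is exact in large samples. Trait noise is
fixed at variance 1 so causal effects are identifiable in recovery
tests. Every stage derives its random state from the scenario seed plus
a fixed offset, so identical configurations reproduce identical data
regardless of call order.

Deliberately absent: linkage disequilibrium (instruments are generated
independent, matching the "independent significant eQTLs" usage; the
`pleiotropy` option shares eQTLs across neighbouring genes to exercise
the multivariable MR path, which is the only cross-SNP structure the
downstream methods consume), cell-type mixtures, non-Gaussian
expression, X-chromosome dosage compensation, and relatedness. Passing
tests therefore demonstrate the statistical machinery is correct under
its own assumptions — not that those assumptions hold in any real
cohort.

# Numerical choices and degenerate inputs

* P-values are clamped to `[.Machine$double.xmin, 1]` so they stay in
  $(0,1]$ even for perfect associations.
* Missing genotypes are `NA`; every statistic drops incomplete
  observations pairwise, and a pair or stratum with fewer than 3
  complete cases is skipped with a collected warning.
* Sex labels are the literal strings `"F"`/`"M"`; numeric codings are
  rejected outright to preclude silent 0/1-vs-1/2 confusion.
* `twmrFit()` refuses design matrices with condition number above
  `1e8` and advises stronger pruning; a gene with fewer than 3
  instruments is skipped with a message rather than fit badly.
* The effective-test count rounds eigenvalues within `1e-8` of an
  integer before taking floors, otherwise floating-point noise near
  integer eigenvalues (e.g. perfectly correlated blocks) doubles the
  count.
* Tables serialize with 10 significant digits; a written table re-read
  and re-written is byte-identical.

# Problem sizes used in the test suite

The shipped checks run at sizes a laptop handles in about a minute
apiece: calibration of the difference tests on 5000 SNP–gene pairs at
500 individuals per stratum; FDR control on 100 replicates of a
2000-test mixture with 20% alternatives at $\Delta\beta = 0.3$,
$n = 1500$ per stratum; TWMR recovery and interval coverage over 500
genes with 10 instruments each at $N_{\mathrm{eQTL}} = 3000$,
$N_{\mathrm{GWAS}} = 50000$; contrast calibration over 500 genes;
mediation recovery at 20000 individuals per stratum over 20 replicates;
and end-to-end eGene recovery over 20 seeds of a 10-gene scenario at
2000 per stratum. These sizes were chosen so that Monte-Carlo error is
comfortably inside each acceptance band.

# Known limitations

Trans effects, conditional/secondary eQTLs, heterogeneity-robust MR
variants (outlier-instrument removal, directionality filtering) and
replication-cohort harmonization are out of scope. The power model
assumes a shared causal effect across sexes and full mediation; if
mediation is partial, the model's required sample sizes are lower
bounds. The upper-tail power formula overstates exact two-sided power
by up to a factor of two in the mid-power regime; use
`exactTwoSided = TRUE` when that matters.
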