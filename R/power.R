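#' @importFrom stats qnorm
NULL

#' Default critical value for the sex-difference rejection rule
#'
#' The power model rejects equality of the sex-specific GWAS effects when
#' the z-style difference statistic exceeds the genome-wide two-sided
#' threshold in absolute value. The conventional printed constant is
#' 5.43; recomputing the upper `2.5e-8` quantile of the standard normal
#' gives `qnorm(1 - 2.5e-8) = 5.4513`. Both are supported everywhere a
#' `crit` argument appears, and required sample sizes differ by under 2%
#' between them (see the methods vignette).
#'
#' @param recompute Return the recomputed quantile instead of 5.43.
#' @return The critical value.
#' @export
critValue <- function(recompute = FALSE) {
  if (recompute) qnorm(1 - 2.5e-8) else 5.43
}

#' Noncentrality of the sex-difference statistic under full mediation
#'
#' When the SNP-trait association is fully mediated by expression with a
#' shared causal effect `alpha`, the expected difference between the
#' sex-specific GWAS effects is `alpha * (betaEqtlF - betaEqtlM)` and the
#' difference statistic is normal with unit variance and mean
#' `ncp = alpha * (betaEqtlF - betaEqtlM) /
#'        sqrt(1/nGwasF + 1/nGwasM)`.
#'
#' All arguments are vectorized.
#'
#' @param alphaTwmr Causal effect of expression on the trait
#'   (standardized units).
#' @param betaEqtlF,betaEqtlM Standardized eQTL effects per sex.
#' @param nGwasF,nGwasM GWAS sample sizes per sex (> 0).
#' @return The noncentrality parameter.
#' @examples
#' noncentrality(0.05, 0.2, 0.1, 190000, 170000)  # ~1.498
#' @export
noncentrality <- function(alphaTwmr, betaEqtlF, betaEqtlM, nGwasF, nGwasM) {
  if (any(nGwasF <= 0) || any(nGwasM <= 0))
    stop("GWAS sample sizes must be positive")
  alphaTwmr * (betaEqtlF - betaEqtlM) / sqrt(1 / nGwasF + 1 / nGwasM)
}

#' Power to detect a sex-biased GWAS effect mediated by a sex-biased eQTL
#'
#' Analytic power of the two-sided sex-difference test at critical value
#' `crit`. The default mode evaluates the upper-tail approximation
#' `power = 2 * (1 - Phi(crit - |ncp|))`, clipped to `[0, 1]` (the
#' formula exceeds 1 once `|ncp| > crit`); `exactTwoSided = TRUE`
#' evaluates the exact two-sided probability
#' `1 - Phi(crit - |ncp|) + Phi(-crit - |ncp|)`. Both are evaluated at
#' the magnitude of the noncentrality, so power is symmetric in the sign
#' of the mediated difference and strictly increasing in `|ncp|`. The two
#' modes agree to high accuracy whenever the approximate power is below
#' 0.5.
#'
#' @inheritParams noncentrality
#' @param crit Critical value (default [critValue()], 5.43).
#' @param exactTwoSided Use the exact two-sided tail sum.
#' @return `data.frame` with `ncp` and `power`.
#' @export
powerSexDiff <- function(alphaTwmr, betaEqtlF, betaEqtlM, nGwasF, nGwasM,
                         crit = critValue(), exactTwoSided = FALSE) {
  if (any(crit <= 0)) stop("crit must be positive")
  ncp <- noncentrality(alphaTwmr, betaEqtlF, betaEqtlM, nGwasF, nGwasM)
  a <- abs(ncp)
  pw <- if (exactTwoSided)
    pnorm(crit - a, lower.tail = FALSE) + pnorm(-crit - a)
  else
    pmin(pmax(2 * pnorm(crit - a, lower.tail = FALSE), 0), 1)
  data.frame(ncp = ncp, power = pw)
}

#' Required GWAS sample size for a target power
#'
#' Smallest total GWAS sample size (females + males) at which the
#' sex-difference test reaches the target power, given the mediated
#' effect difference `alphaTwmr * (betaF - betaM)` and the female
#' fraction of the total. The power function is monotone in N; the
#' search brackets the closed-form inversion and bisects over even
#' totals so both strata stay integral at a 0.5 ratio.
#'
#' @inheritParams powerSexDiff
#' @param ratioF Fraction of the total that is female, in (0, 1).
#' @param targetPower Target power (default 0.8).
#' @return Total sample size (even integer).
#' @export
requiredSampleSize <- function(alphaTwmr, betaEqtlF, betaEqtlM,
                               ratioF = 0.5, targetPower = 0.8,
                               crit = critValue(), exactTwoSided = FALSE) {
  stopifnot(length(alphaTwmr) == 1L, ratioF > 0, ratioF < 1,
            targetPower > 0, targetPower < 1)
  effect <- alphaTwmr * (betaEqtlF - betaEqtlM)
  if (effect == 0)
    stop("power can never exceed the size: alpha * delta-beta is zero")
  pw <- function(n_total) {
    powerSexDiff(alphaTwmr, betaEqtlF, betaEqtlM,
                 nGwasF = ratioF * n_total, nGwasM = (1 - ratioF) * n_total,
                 crit = crit, exactTwoSided = exactTwoSided)$power
  }
  # closed-form start (paper-mode): ncp* = crit - qnorm(1 - target/2);
  # ncp = |effect| * sqrt(r(1-r)N) => N* = (ncp*/(effect))^2 / (r(1-r))
  ncp_star <- crit - qnorm(1 - targetPower / 2)
  n_guess <- (ncp_star / effect)^2 / (ratioF * (1 - ratioF))
  lo <- 2
  hi <- max(2 * ceiling(n_guess / 2), 4)
  while (pw(hi) < targetPower) hi <- hi * 2
  while (hi - lo > 2) {
    mid <- 2 * floor((lo + hi) / 4)
    if (pw(mid) >= targetPower) hi <- mid else lo <- mid
  }
  if (pw(lo) >= targetPower) lo else hi
}

#' Power and sample-size grids
#'
#' Evaluates the analytic power over the cartesian grid of causal
#' effects, eQTL effect differences and total GWAS sample sizes, plus a
#' companion table of required totals at the target power — the tables
#' behind a power-surface figure.
#'
#' @param alphaValues Causal effects (e.g. quantiles of the significant
#'   TWMR effect distribution).
#' @param deltaBetaValues eQTL effect differences `betaF - betaM`.
#' @param nTotalValues Total GWAS sample sizes.
#' @param ratioF Female fraction of the total (default 0.5).
#' @param crit Critical value (default [critValue()]).
#' @param targetPower Target power for the sample-size table (default
#'   0.8).
#' @return List with `power` (`alpha`, `delta_beta`, `n_total`, `ncp`,
#'   `power`; one row per grid cell) and `sampleSize` (`alpha`,
#'   `delta_beta`, `n_required`).
#' @export
powerGrid <- function(alphaValues, deltaBetaValues, nTotalValues,
                      ratioF = 0.5, crit = critValue(), targetPower = 0.8) {
  stopifnot(length(alphaValues) > 0, length(deltaBetaValues) > 0,
            length(nTotalValues) > 0)
  g <- expand.grid(alpha = alphaValues, delta_beta = deltaBetaValues,
                   n_total = nTotalValues, KEEP.OUT.ATTRS = FALSE)
  pw <- powerSexDiff(g$alpha, g$delta_beta, 0,
                     nGwasF = ratioF * g$n_total,
                     nGwasM = (1 - ratioF) * g$n_total, crit = crit)
  power <- cbind(g, pw)
  ss <- expand.grid(alpha = alphaValues, delta_beta = deltaBetaValues,
                    KEEP.OUT.ATTRS = FALSE)
  ss$n_required <- mapply(function(a, d) {
    if (a * d == 0) return(NA_real_)
    requiredSampleSize(a, d, 0, ratioF = ratioF,
                       targetPower = targetPower, crit = crit)
  }, ss$alpha, ss$delta_beta)
  list(power = power, sampleSize = ss)
}
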