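#' @importFrom stats pnorm pf p.adjust wilcox.test phyper var
NULL

.clamp_p <- function(p) pmin(pmax(p, .Machine$double.xmin), 1)

#' Sex-difference test for standardized eQTL effects
#'
#' Tests the difference between the female- and male-specific
#' standardized eQTL effects with
#' `t = (betaF - betaM) / sqrt(1/nF + 1/nM)` and a two-sided p-value from
#' the standard normal. The `1/n` denominators are the large-sample
#' variances of standardized (rank-correlation scale) effects.
#'
#' All arguments are vectorized.
#'
#' @param betaF,betaM Standardized effects per stratum.
#' @param nF,nM Per-stratum sample sizes (>= 2).
#' @return `data.frame` with columns `delta` (female minus male),
#'   `statistic`, `p_diff`.
#' @examples
#' eqtlDiffTest(0.5, 0.3, 1928, 1519)  # t = 5.83
#' @export
eqtlDiffTest <- function(betaF, betaM, nF, nM) {
  if (any(nF <= 0) || any(nM <= 0)) stop("sample sizes must be positive")
  delta <- betaF - betaM
  stat <- delta / sqrt(1 / nF + 1 / nM)
  data.frame(delta = delta, statistic = stat,
             p_diff = .clamp_p(2 * pnorm(-abs(stat))))
}

#' Sex-difference test for GWAS effects
#'
#' Tests the difference between the female- and male-specific GWAS
#' effects with `t = (betaF - betaM) / sqrt(seF^2 + seM^2)` and a
#' two-sided standard-normal p-value. `delta` is the effect difference
#' (the quantity often written theta).
#'
#' @param betaF,betaM Per-stratum effects.
#' @param seF,seM Per-stratum standard errors (> 0).
#' @return `data.frame` with `delta`, `statistic`, `p_diff`.
#' @examples
#' gwasDiffTest(0.10, 0.01, 0.06, 0.01)  # t = 2.828
#' @export
gwasDiffTest <- function(betaF, seF, betaM, seM) {
  if (any(seF <= 0) || any(seM <= 0)) stop("standard errors must be positive")
  delta <- betaF - betaM
  stat <- delta / sqrt(seF^2 + seM^2)
  data.frame(delta = delta, statistic = stat,
             p_diff = .clamp_p(2 * pnorm(-abs(stat))))
}

#' Per-gene, per-stratum expression summaries
#'
#' Computes for each gene and each sex stratum the mean, standard error
#' of the mean, sample variance and sample size — the inputs of the
#' expression mean and variance dimorphism tests.
#'
#' @param expression An [ExpressionExperiment-class].
#' @param sex Per-individual labels; defaults to those stored in the
#'   object.
#' @return `data.frame` with one row per gene: `gene_id`, and per stratum
#'   `mean_F`, `sem_F`, `var_F`, `n_F` (likewise `_M`).
#' @export
expressionSummary <- function(expression, sex = sexLabels(expression)) {
  E <- exprMatrix(expression)
  out <- lapply(c("F", "M"), function(s) {
    Es <- E[sex == s, , drop = FALSE]
    n <- nrow(Es)
    v <- apply(Es, 2L, var)
    data.frame(mean = colMeans(Es), sem = sqrt(v / n), var = v, n = n)
  })
  data.frame(gene_id = colnames(E),
             mean_F = out[[1L]]$mean, sem_F = out[[1L]]$sem,
             var_F = out[[1L]]$var, n_F = out[[1L]]$n,
             mean_M = out[[2L]]$mean, sem_M = out[[2L]]$sem,
             var_M = out[[2L]]$var, n_M = out[[2L]]$n,
             row.names = NULL)
}

#' Expression mean dimorphism test
#'
#' Tests the difference in mean expression between the sexes with
#' `t = (muF - muM) / sqrt(semF^2 + semM^2)`, where `sem` is the standard
#' error of the mean per stratum, and a two-sided standard-normal
#' p-value.
#'
#' @param summary `data.frame` from [expressionSummary()] (or any table
#'   with `mean_F`, `sem_F`, `mean_M`, `sem_M` columns).
#' @return `data.frame` with `gene_id` (when present), `delta`,
#'   `statistic`, `p_diff`.
#' @export
deMeanTest <- function(summary) {
  if (any(summary$sem_F <= 0) || any(summary$sem_M <= 0))
    stop("standard errors must be positive")
  res <- gwasDiffTest(summary$mean_F, summary$sem_F,
                      summary$mean_M, summary$sem_M)
  if ("gene_id" %in% colnames(summary))
    res <- cbind(gene_id = summary$gene_id, res)
  res
}

#' Expression variance dimorphism F-test
#'
#' Tests equality of expression variance between the sexes with the
#' variance ratio `F = varF / varM` and a two-sided p-value
#' `2 * min(P(F > f), P(F < f))` capped at 1. The reference distribution
#' uses the statistically standard degrees of freedom
#' `(nF - 1, nM - 1)`; `dfAsPrinted = TRUE` switches to `(nF, nM)`, the
#' convention some reports print.
#'
#' @param varF,varM Per-stratum sample variances (`varM > 0`).
#' @param nF,nM Per-stratum sample sizes (>= 2).
#' @param dfAsPrinted Use `(nF, nM)` degrees of freedom instead of
#'   `(nF - 1, nM - 1)`.
#' @return `data.frame` with `delta` (variance ratio minus 1 is not used;
#'   `delta = varF - varM`), `statistic` (the F ratio), `p_diff`.
#' @export
varianceFTest <- function(varF, varM, nF, nM, dfAsPrinted = FALSE) {
  if (any(varM <= 0)) stop("male variance must be positive")
  if (any(varF < 0)) stop("variances must be non-negative")
  if (any(nF < 2) || any(nM < 2)) stop("need at least 2 per stratum")
  f <- varF / varM
  df1 <- if (dfAsPrinted) nF else nF - 1
  df2 <- if (dfAsPrinted) nM else nM - 1
  lower <- pf(f, df1, df2)
  upper <- pf(f, df1, df2, lower.tail = FALSE)
  p <- ifelse(varF == 0, lower, pmin(2 * pmin(lower, upper), 1))
  data.frame(delta = varF - varM, statistic = f, p_diff = .clamp_p(p))
}

#' Benjamini-Hochberg FDR selection
#'
#' Step-up FDR control: q-values via the Benjamini-Hochberg adjustment, a
#' selection mask at level `qLevel`, and the p-value threshold (the
#' largest selected p — the form in which FDR cutoffs are usually
#' reported).
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`.
#' @param qLevel Nominal FDR level (default 0.05).
#' @return List with `q` (adjusted p-values), `selected` (logical mask)
#'   and `pThreshold` (largest selected p, `NA` if none).
#' @export
bhFdr <- function(pvalues, qLevel = 0.05) {
  if (!length(pvalues))
    return(list(q = numeric(), selected = logical(), pThreshold = NA_real_))
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  q <- p.adjust(pvalues, method = "BH")
  selected <- q <= qLevel
  list(q = q, selected = selected,
       pThreshold = if (any(selected)) max(pvalues[selected]) else NA_real_)
}

#' Pick the lead eQTL per gene
#'
#' Returns, for each gene, the record with the strongest sex-difference:
#' maximum `|statistic|`, ties broken by smaller `p_diff`, then by
#' lexicographically smallest `snp_id`.
#'
#' @param diffResults `data.frame` with at least `snp_id`, `statistic`,
#'   `p_diff` and the grouping column.
#' @param groupCol Name of the gene column (default `"unit_id"`).
#' @return One row per group, in group order of first appearance.
#' @export
pickLeadEqtl <- function(diffResults, groupCol = "unit_id") {
  stopifnot(nrow(diffResults) > 0, groupCol %in% colnames(diffResults))
  ord <- order(-abs(diffResults$statistic), diffResults$p_diff,
               diffResults$snp_id)
  sorted <- diffResults[ord, , drop = FALSE]
  lead <- sorted[!duplicated(sorted[[groupCol]]), , drop = FALSE]
  lead[match(unique(diffResults[[groupCol]]), lead[[groupCol]]), ,
       drop = FALSE]
}

#' Hypergeometric enrichment of two gene sets
#'
#' Upper-tail hypergeometric test for the overlap `k` of two sets of
#' sizes `nSetA` and `nSetB` drawn from a universe of `nUniverse`:
#' `p = P(X >= k)`. The odds ratio comes from the 2x2 table,
#' `OR = k * (U - A - B + k) / ((A - k) * (B - k))` (infinite when a
#' margin is exhausted).
#'
#' @param kOverlap Observed overlap.
#' @param nSetA,nSetB Set sizes.
#' @param nUniverse Universe size.
#' @return List with `odds_ratio` and `p`.
#' @export
hypergeomEnrichment <- function(kOverlap, nSetA, nSetB, nUniverse) {
  k <- kOverlap
  if (k < 0 || nSetA > nUniverse || nSetB > nUniverse ||
      k > min(nSetA, nSetB) || k < max(0, nSetA + nSetB - nUniverse))
    stop("impossible 2x2 counts")
  p <- phyper(k - 1, nSetA, nUniverse - nSetA, nSetB, lower.tail = FALSE)
  d <- (nSetA - k) * (nSetB - k)
  or <- if (d == 0) Inf else k * (nUniverse - nSetA - nSetB + k) / d
  list(odds_ratio = or, p = .clamp_p(p))
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test comparing the two sex strata: exact
#' enumeration when the combined sample size is at most 20 and there are
#' no ties, otherwise the normal approximation with tie correction (no
#' continuity correction).
#'
#' @param valuesF,valuesM Numeric vectors (each non-empty).
#' @return List with `statistic` (the rank-sum `W` of the first sample)
#'   and `p`.
#' @export
wilcoxonRankSum <- function(valuesF, valuesM) {
  if (!length(valuesF) || !length(valuesM)) stop("both groups must be non-empty")
  n <- length(valuesF) + length(valuesM)
  ties <- anyDuplicated(c(valuesF, valuesM)) > 0L
  wt <- suppressWarnings(wilcox.test(valuesF, valuesM,
                                     exact = n <= 20L && !ties,
                                     correct = FALSE))
  list(statistic = unname(wt$statistic), p = .clamp_p(wt$p.value))
}

#' Levene's test for variance dimorphism (two groups)
#'
#' Levene's statistic on absolute deviations from the group mean:
#' a one-way ANOVA F statistic on `|x - mean(group)|` with
#' `(1, nF + nM - 2)` degrees of freedom. Location-free: adding a
#' constant to either group leaves it unchanged.
#'
#' @param valuesF,valuesM Numeric vectors (each of length >= 2).
#' @return List with `statistic` and `p`.
#' @export
leveneTest <- function(valuesF, valuesM) {
  if (length(valuesF) < 2L || length(valuesM) < 2L)
    stop("each group needs at least 2 observations")
  zf <- abs(valuesF - mean(valuesF))
  zm <- abs(valuesM - mean(valuesM))
  nf <- length(zf); nm <- length(zm); n <- nf + nm
  zbar <- mean(c(zf, zm))
  ssb <- nf * (mean(zf) - zbar)^2 + nm * (mean(zm) - zbar)^2
  ssw <- sum((zf - mean(zf))^2) + sum((zm - mean(zm))^2)
  if (ssw == 0) {
    stat <- if (ssb == 0) 0 else Inf
  } else {
    stat <- (ssb / 1) / (ssw / (n - 2))
  }
  p <- if (is.infinite(stat)) .Machine$double.xmin
       else .clamp_p(pf(stat, 1, n - 2, lower.tail = FALSE))
  list(statistic = stat, p = p)
}

#' Effective number of independent tests
#'
#' Li-Ji-style eigenvalue estimate of the effective number of independent
#' phenotypes in a correlation matrix:
#' `m_eff = sum_j [ 1(lambda_j >= 1) + (lambda_j - floor(lambda_j)) ]`,
#' clamped to `[1, m]`. With unit diagonal the sum is integer-valued.
#'
#' @param corMat Symmetric correlation matrix with unit diagonal.
#' @return Integer `m_eff`.
#' @examples
#' effectiveTests(diag(39))  # 39
#' @export
effectiveTests <- function(corMat) {
  if (!is.matrix(corMat) || !isSymmetric(unname(corMat), tol = 1e-8))
    stop("corMat must be a symmetric matrix")
  lam <- eigen(corMat, symmetric = TRUE, only.values = TRUE)$values
  near_int <- abs(lam - round(lam)) < 1e-8  # guard floor() against FP noise
  lam[near_int] <- round(lam[near_int])
  lam[lam < 0] <- 0
  meff <- sum((lam >= 1) + (lam - floor(lam)))
  as.integer(min(max(round(meff), 1L), nrow(corMat)))
}

#' Sex-difference scan over two summary-statistic tables
#'
#' Merges a female and a male summary-statistic table on
#' `(snp_id, unit_id)` and applies the appropriate difference test per
#' row: the standardized-effect test ([eqtlDiffTest()], denominators
#' `1/n`) when the tables follow the standardized convention, otherwise
#' the explicit-standard-error test ([gwasDiffTest()]). Benjamini-
#' Hochberg q-values at `qLevel` are appended.
#'
#' @param tableF,tableM Summary-statistic tables for the two strata.
#' @param qLevel FDR level for the appended selection (default 0.05).
#' @return `data.frame` with `snp_id`, `unit_id`, per-stratum effects,
#'   `delta`, `statistic`, `p_diff`, `q`, `selected`; attribute
#'   `"pThreshold"` carries the realized p cutoff.
#' @export
diffTestTables <- function(tableF, tableM, qLevel = 0.05) {
  keyF <- paste(tableF$snp_id, tableF$unit_id)
  keyM <- paste(tableM$snp_id, tableM$unit_id)
  common <- intersect(keyF, keyM)
  if (!length(common)) stop("no shared (snp_id, unit_id) keys")
  iF <- match(common, keyF)
  iM <- match(common, keyM)
  standardized <- isTRUE(attr(tableF, "standardized")) ||
    all(is.na(tableF$se[iF]))
  res <- if (standardized)
    eqtlDiffTest(tableF$beta[iF], tableM$beta[iM], tableF$n[iF], tableM$n[iM])
  else
    gwasDiffTest(tableF$beta[iF], tableF$se[iF],
                 tableM$beta[iM], tableM$se[iM])
  fdr <- bhFdr(res$p_diff, qLevel)
  out <- data.frame(snp_id = tableF$snp_id[iF], unit_id = tableF$unit_id[iF],
                    beta_F = tableF$beta[iF], beta_M = tableM$beta[iM],
                    res, q = fdr$q, selected = fdr$selected,
                    row.names = NULL)
  attr(out, "pThreshold") <- fdr$pThreshold
  out
}
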