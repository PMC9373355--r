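#' @importFrom stats median
NULL

#' Build an instrument set for one focal gene
#'
#' Selects, from a (per-stratum) eQTL summary-statistic table, the
#' instruments of a focal gene: SNPs with eQTL `p < pInst` (default
#' 1e-3), greedily pruned to pairwise `r^2 < r2Prune` keeping the
#' smallest p-value first. Every other gene for which any retained SNP is
#' also a significant eQTL (`p < pInst`) enters as an additional exposure
#' column, giving the multivariable design matrix. SNP-trait effects are
#' taken from the matching GWAS table; a retained instrument with no GWAS
#' record is an error.
#'
#' Genes with fewer than 3 surviving instruments are skipped: the
#' function emits a message and returns `NULL`.
#'
#' @param eqtlTable Standardized eQTL summary statistics (one stratum).
#' @param gwasTable GWAS summary statistics for the same stratum; the
#'   trait is whatever `unit_id` the table carries.
#' @param focalGene Gene identifier.
#' @param pInst Instrument significance threshold (default 1e-3).
#' @param r2Prune Pairwise `r^2` above which the weaker instrument is
#'   dropped (default 0.1).
#' @param ld Optional SNP correlation matrix (dimnames = SNP ids);
#'   identity assumed when `NULL` (independent instruments).
#' @param nEqtl,nGwas Sample sizes behind the two tables; defaults to the
#'   median `n` of the respective rows.
#' @return List of class `"InstrumentSet"` with elements `focal_gene`,
#'   `snp_ids`, `E` (k x g effect matrix, focal gene first), `G` (k
#'   SNP-trait effects), `C` (k x k instrument correlation), `n_eqtl`,
#'   `n_gwas` — or `NULL` when the instrument floor of 3 is not met.
#' @export
buildInstrumentSet <- function(eqtlTable, gwasTable, focalGene,
                               pInst = 1e-3, r2Prune = 0.1, ld = NULL,
                               nEqtl = NULL, nGwas = NULL) {
  cand <- eqtlTable[eqtlTable$unit_id == focalGene & eqtlTable$p < pInst, ,
                    drop = FALSE]
  cand <- cand[order(cand$p, cand$snp_id), , drop = FALSE]
  keep <- character()
  for (s in cand$snp_id) {
    if (is.null(ld) || !length(keep)) r2 <- 0
    else r2 <- max(ld[s, keep, drop = TRUE]^2, na.rm = TRUE)
    if (!length(keep) || r2 < r2Prune) keep <- c(keep, s)
  }
  if (length(keep) < 3L) {
    message(sprintf(
      "gene %s skipped: %d instrument(s) after selection/pruning (floor is 3)",
      focalGene, length(keep)))
    return(NULL)
  }
  co <- eqtlTable[eqtlTable$snp_id %in% keep & eqtlTable$p < pInst, ,
                  drop = FALSE]
  genes <- c(focalGene, setdiff(unique(co$unit_id), focalGene))
  E <- matrix(0, length(keep), length(genes),
              dimnames = list(keep, genes))
  rows <- eqtlTable[eqtlTable$snp_id %in% keep &
                      eqtlTable$unit_id %in% genes, , drop = FALSE]
  E[cbind(match(rows$snp_id, keep), match(rows$unit_id, genes))] <- rows$beta
  gi <- match(keep, gwasTable$snp_id)
  if (anyNA(gi))
    stop("no GWAS effect for instrument SNP: ", keep[which(is.na(gi))[1L]])
  G <- gwasTable$beta[gi]
  C <- if (is.null(ld)) diag(length(keep)) else ld[keep, keep, drop = FALSE]
  dimnames(C) <- list(keep, keep)
  inst <- list(focal_gene = focalGene, snp_ids = keep, E = E, G = G, C = C,
               n_eqtl = nEqtl %||% as.integer(round(median(cand$n))),
               n_gwas = nGwas %||% as.integer(round(median(gwasTable$n[gi]))))
  class(inst) <- "InstrumentSet"
  inst
}

#' Multivariable TWMR causal-effect estimate
#'
#' Estimates the causal effect of expression on the trait from summary
#' statistics by multivariable inverse-variance-weighted MR with LD
#' weighting:
#' `alpha_hat = (E' C^-1 E)^-1 E' C^-1 G`.
#' With identity `C` and a single exposure this reduces to the IVW ratio
#' estimator `sum(E_i G_i) / sum(E_i^2)`.
#'
#' Standard errors propagate the sampling noise of both summary inputs.
#' The default (`seMethod = "delta"`) is the first-order delta-method
#' variance
#' `var(alpha_hat) = diag((E'C^-1 E)^-1) * (1/n_gwas +
#' sum(alpha_hat^2)/n_eqtl)`,
#' which accounts for the eQTL-effect noise in proportion to the
#' estimated causal effects. `seMethod = "inflation"` uses the cruder
#' `diag((E'C^-1 E)^-1) * (1/n_gwas + 1/n_eqtl)`, an upper bound that is
#' conservative whenever `|alpha| < 1`.
#'
#' @param inst An `"InstrumentSet"` from [buildInstrumentSet()], or any
#'   list with elements `E`, `G`, `C`, `n_eqtl`, `n_gwas`,
#'   `focal_gene`.
#' @param stratum Label recorded in the output (default `"combined"`).
#' @param seMethod `"delta"` (default) or `"inflation"`, see Details.
#' @return `data.frame` of class `c("TwmrFit", "data.frame")`, one row
#'   per exposure (focal gene first): `gene_id`, `stratum`, `alpha`,
#'   `se`, `p`, `k_instruments`, `g_exposures`, `focal`.
#' @export
twmrFit <- function(inst, stratum = "combined",
                    seMethod = c("delta", "inflation")) {
  seMethod <- match.arg(seMethod)
  E <- inst$E; G <- inst$G; C <- inst$C
  k <- nrow(E)
  if (k < 3L) stop("instrument floor is 3 (got ", k, ")")
  CinvE <- solve(C, E)
  A <- crossprod(E, CinvE)
  if (kappa(A, exact = TRUE) > 1e8)
    stop("E'C^-1E is near-singular (condition number > 1e8); ",
         "prune instruments more aggressively or drop exposures")
  Ainv <- solve(A)
  alpha <- as.vector(Ainv %*% crossprod(CinvE, G))
  fac <- switch(seMethod,
                delta = 1 / inst$n_gwas + sum(alpha^2) / inst$n_eqtl,
                inflation = 1 / inst$n_gwas + 1 / inst$n_eqtl)
  se <- sqrt(diag(Ainv) * fac)
  p <- .clamp_p(2 * pnorm(-abs(alpha / se)))
  out <- data.frame(gene_id = colnames(E), stratum = stratum,
                    alpha = alpha, se = se, p = p,
                    k_instruments = k, g_exposures = ncol(E),
                    focal = colnames(E) == inst$focal_gene,
                    row.names = NULL)
  class(out) <- c("TwmrFit", "data.frame")
  out
}

#' Sex contrast on TWMR causal effects
#'
#' Tests, gene by gene, whether the causal effect of expression on the
#' trait differs between females and males:
#' `t = (alphaF - alphaM) / sqrt(seF^2 + seM^2)` with a two-sided
#' standard-normal p-value. A Bonferroni significance threshold
#' `0.05 / n_genes_tested` is attached.
#'
#' @param fitF,fitM `"TwmrFit"` tables for the two strata. Only rows with
#'   `focal = TRUE` (or all rows, when the column is absent) are
#'   contrasted, matched on `gene_id`.
#' @param bonferroniLevel Family-wise level for the attached threshold
#'   (default 0.05).
#' @return `data.frame` with `gene_id`, `alpha_F`, `alpha_M`, `delta`,
#'   `statistic`, `p_diff`, `significant`; attribute
#'   `"bonferroniThreshold"`.
#' @export
twmrSexContrast <- function(fitF, fitM, bonferroniLevel = 0.05) {
  if ("focal" %in% colnames(fitF)) fitF <- fitF[fitF$focal, , drop = FALSE]
  if ("focal" %in% colnames(fitM)) fitM <- fitM[fitM$focal, , drop = FALSE]
  common <- intersect(fitF$gene_id, fitM$gene_id)
  if (!length(common)) stop("no gene present in both strata's fits")
  iF <- match(common, fitF$gene_id)
  iM <- match(common, fitM$gene_id)
  res <- gwasDiffTest(fitF$alpha[iF], fitF$se[iF],
                      fitM$alpha[iM], fitM$se[iM])
  thr <- bonferroniLevel / length(common)
  out <- data.frame(gene_id = common,
                    alpha_F = fitF$alpha[iF], alpha_M = fitM$alpha[iM],
                    res, significant = res$p_diff < thr, row.names = NULL)
  attr(out, "bonferroniThreshold") <- thr
  out
}
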