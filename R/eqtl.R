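#' @importFrom stats cor prcomp pnorm lm.fit
NULL

#' Select cis SNP-gene pairs
#'
#' A SNP-gene pair is tested when the gene's center position lies within
#' `halfWidth` base pairs of the SNP (1 Mb upstream and 1 Mb downstream by
#' default) on the same chromosome. The boundary is inclusive. Pairs are
#' returned in deterministic `(chrom, snp_pos, gene_id)` order.
#'
#' @param genotypes A [GenotypeExperiment-class].
#' @param expression An [ExpressionExperiment-class].
#' @param halfWidth Window half-width in base pairs (default 1e6).
#' @return `data.frame` with columns `snp_id`, `gene_id`.
#' @export
selectCisPairs <- function(genotypes, expression, halfWidth = 1e6) {
  stopifnot(halfWidth > 0)
  sn <- snpInfo(genotypes)
  ge <- geneInfo(expression)
  win <- GRanges(sn$chrom,
                 IRanges(start = pmax(1, sn$pos - halfWidth),
                         end = sn$pos + halfWidth))
  centers <- GRanges(ge$chrom, IRanges(start = ge$center_pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(win, centers)
  pairs <- data.frame(snp_id = sn$snp_id[S4Vectors::queryHits(hits)],
                      gene_id = ge$gene_id[S4Vectors::subjectHits(hits)],
                      chrom = sn$chrom[S4Vectors::queryHits(hits)],
                      snp_pos = sn$pos[S4Vectors::queryHits(hits)])
  pairs <- pairs[order(pairs$chrom, pairs$snp_pos, pairs$gene_id), ]
  rownames(pairs) <- NULL
  pairs[, c("snp_id", "gene_id")]
}

#' Residualize expression on genetics-free principal components
#'
#' Computes the first `nPcs` principal components of the expression matrix
#' (individuals by genes, centered), screens each against every SNP by
#' simple regression, drops any component whose smallest association
#' p-value falls below `assocPThreshold` (those components carry genetic
#' signal that must not be regressed out), and returns the residuals of
#' expression on the retained components. The retained/dropped component
#' report is stored in `metadata()` of the returned object.
#'
#' @param expression An [ExpressionExperiment-class].
#' @param genotypes A [GenotypeExperiment-class] on the same individuals.
#' @param nPcs Number of leading components to consider (default 25).
#' @param assocPThreshold Association p-value below which a component is
#'   considered genetic and dropped (default 1e-12).
#' @return A new [ExpressionExperiment-class] of residuals, with
#'   `metadata()$pc_report` listing `retained`, `dropped` and the per-PC
#'   minimum association p-value.
#' @export
residualizePCs <- function(expression, genotypes, nPcs = 25,
                           assocPThreshold = 1e-12) {
  if (nPcs <= 0) stop("nPcs must be a positive integer")
  E <- exprMatrix(expression)
  X <- dosageMatrix(genotypes)
  stopifnot(nrow(E) == nrow(X))
  if (nPcs >= nrow(E)) stop("nPcs must be smaller than the number of individuals")
  nPcs <- min(nPcs, ncol(E))
  pca <- prcomp(E, center = TRUE, scale. = FALSE)
  nPcs <- min(nPcs, ncol(pca$x))
  scores <- pca$x[, seq_len(nPcs), drop = FALSE]
  # min association p of each PC against all SNPs (simple regression)
  minp <- apply(scores, 2L, function(pc) {
    r <- suppressWarnings(as.vector(cor(X, pc, use = "pairwise.complete.obs")))
    n <- colSums(!is.na(X))
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    min(2 * pt(-abs(tt), df = n - 2), na.rm = TRUE)
  })
  drop <- minp < assocPThreshold
  retained <- scores[, !drop, drop = FALSE]
  if (ncol(retained)) {
    fit <- lm.fit(cbind(1, retained), E)
    R <- fit$residuals
  } else {
    R <- sweep(E, 2L, colMeans(E), `-`)
  }
  ge <- geneInfo(expression)
  out <- ExpressionExperiment(R, geneId = ge$gene_id, chrom = ge$chrom,
                              centerPos = ge$center_pos,
                              sex = .sex_from_coldata(expression, FALSE))
  metadata(out)$pc_report <- list(
    n_pcs = nPcs,
    retained = colnames(scores)[!drop],
    dropped = colnames(scores)[drop],
    min_assoc_p = minp,
    assoc_p_threshold = assocPThreshold)
  out
}

#' Sex-stratified cis-eQTL mapping by rank correlation
#'
#' For each cis SNP-gene pair, computes the Spearman rank correlation
#' between dosage and expression over the stratum's complete cases (ties
#' resolved by average ranks) and a two-sided p-value via the
#' t-approximation `t = r * sqrt((n - 2) / (1 - r^2))`. The standardized
#' effect is the rank correlation itself, with the large-sample variance
#' convention `var(beta_hat) = 1/n` (so the table carries `se = NA` and
#' `attr(,"standardized") = TRUE`).
#'
#' Pairs with fewer than 3 complete observations are skipped with a
#' warning.
#'
#' @param genotypes A [GenotypeExperiment-class].
#' @param expression An [ExpressionExperiment-class] on the same
#'   individuals.
#' @param pairs `data.frame` with `snp_id`, `gene_id` columns, e.g. from
#'   [selectCisPairs()].
#' @param stratum `"F"`, `"M"` or `"combined"` (all individuals).
#' @param sex Per-individual labels; defaults to those stored in
#'   `genotypes`.
#' @return Summary-statistic `data.frame` in the [readSummaryStats()]
#'   layout (standardized convention).
#' @export
mapEqtls <- function(genotypes, expression, pairs,
                     stratum = c("F", "M", "combined"),
                     sex = NULL) {
  stratum <- match.arg(stratum)
  X <- dosageMatrix(genotypes)
  E <- exprMatrix(expression)
  stopifnot(nrow(X) == nrow(E))
  if (stratum != "combined") {
    if (is.null(sex)) sex <- sexLabels(genotypes)
    keep <- sex == stratum
    if (!any(keep)) stop("stratum ", stratum, " is empty")
    X <- X[keep, , drop = FALSE]
    E <- E[keep, , drop = FALSE]
  }
  si <- match(pairs$snp_id, colnames(X))
  gi <- match(pairs$gene_id, colnames(E))
  if (anyNA(si)) stop("unknown snp_id in pairs: ", pairs$snp_id[which(is.na(si))[1L]])
  if (anyNA(gi)) stop("unknown gene_id in pairs: ", pairs$gene_id[which(is.na(gi))[1L]])
  n_all <- nrow(X)
  complete <- !(is.na(X[, si, drop = FALSE]) | is.na(E[, gi, drop = FALSE]))
  n_pair <- colSums(complete)
  # fast path: rank once per column when there are no missing values
  has_na <- anyNA(X) || anyNA(E)
  if (!has_na) {
    Xr <- scale(apply(X, 2L, rank))
    Er <- scale(apply(E, 2L, rank))
    r <- colSums(Xr[, si, drop = FALSE] * Er[, gi, drop = FALSE]) / (n_all - 1)
  } else {
    r <- vapply(seq_along(si), function(k) {
      ok <- complete[, k]
      if (sum(ok) < 3L) return(NA_real_)
      suppressWarnings(cor(X[ok, si[k]], E[ok, gi[k]], method = "spearman"))
    }, numeric(1L))
  }
  skip <- n_pair < 3L | !is.finite(r)
  if (any(skip))
    warning(sprintf("%d pair(s) with fewer than 3 complete cases or constant values skipped",
                    sum(skip)))
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n_pair - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n_pair - 2)
  p[r == 1 | r == -1] <- .Machine$double.xmin
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  res <- data.frame(snp_id = pairs$snp_id, unit_id = pairs$gene_id,
                    stratum = stratum, beta = r, se = NA_real_,
                    n = as.integer(n_pair), p = p, row.names = NULL)
  res <- res[!skip, , drop = FALSE]
  attr(res, "standardized") <- TRUE
  res
}

#' Fixed-effect meta-analysis of the two sex strata
#'
#' Combines female and male standardized effects per SNP-gene key by
#' inverse-variance weighting under the `var = 1/n` convention:
#' `beta_c = (nF*betaF + nM*betaM) / (nF + nM)`,
#' `z = beta_c * sqrt(nF + nM)`, with a two-sided standard-normal
#' p-value.
#'
#' @param tableF,tableM Standardized summary-statistic tables for the two
#'   strata with matching `(snp_id, unit_id)` keys.
#' @return Combined summary-statistic `data.frame` with
#'   `stratum = "combined"`.
#' @export
metaAnalyze <- function(tableF, tableM) {
  keyF <- paste(tableF$snp_id, tableF$unit_id)
  keyM <- paste(tableM$snp_id, tableM$unit_id)
  missing <- c(setdiff(keyF, keyM), setdiff(keyM, keyF))
  if (length(missing))
    stop("keys present in only one stratum: ",
         paste(utils::head(missing, 5L), collapse = "; "),
         if (length(missing) > 5L) sprintf(" (and %d more)", length(missing) - 5L))
  j <- match(keyF, keyM)
  nF <- tableF$n
  nM <- tableM$n[j]
  beta_c <- (nF * tableF$beta + nM * tableM$beta[j]) / (nF + nM)
  z <- beta_c * sqrt(nF + nM)
  p <- pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
  res <- data.frame(snp_id = tableF$snp_id, unit_id = tableF$unit_id,
                    stratum = "combined", beta = beta_c, se = NA_real_,
                    n = as.integer(nF + nM), p = p, row.names = NULL)
  attr(res, "standardized") <- TRUE
  res
}
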