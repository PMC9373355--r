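#' @importFrom stats rbinom rnorm runif sd pt
NULL

#' Simulation scenario parameters
#'
#' Builds and validates the parameter set for the synthetic-data generator.
#' The generator emulates the statistical structure assumed by the
#' sex-stratified analysis chain: Hardy-Weinberg genotypes at configurable
#' minor allele frequency, standardized per-sex eQTL effects of the same
#' sign but possibly different magnitude, per-sex expression noise, and a
#' trait generated under the mediation model
#' `beta_GWAS(s) = alpha(s) * beta_eQTL(s)` plus optional direct SNP
#' effects.
#'
#' Female and male effect sizes apply to SNP-gene pairs flagged as
#' sex-biased (a fraction `fracSexBiased` of all pairs, chosen at random
#' under the scenario seed); unbiased pairs share the male effect in both
#' sexes. Defaults mirror a blood eQTL study of 1928 women and 1519 men
#' with moderate standardized cis effects.
#'
#' All generator functions are deterministic given the same `SimParams`:
#' each derives its random state from `seed` plus a fixed per-stage offset.
#'
#' @param nF,nM Number of female / male individuals (each >= 2).
#' @param nGenes Number of genes (one locus per gene, > 2 Mb apart).
#' @param nSnpsPerGene Number of cis SNPs per gene, all within +/- 1 Mb of
#'   the gene center.
#' @param mafRange Minor-allele-frequency interval within (0, 0.5) from
#'   which per-SNP MAFs are drawn uniformly.
#' @param betaF,betaM Standardized per-allele eQTL effect in females /
#'   males for sex-biased pairs (scalar or one value per SNP-gene pair);
#'   unbiased pairs use `betaM` in both sexes.
#' @param sdExprF,sdExprM Expression noise standard deviation per sex
#'   (scalar or one value per gene); must be positive.
#' @param alphaF,alphaM Causal effect of each gene's expression on the
#'   trait per sex (scalar or per gene).
#' @param directSnpEffectSd Standard deviation of direct (non-mediated)
#'   standardized SNP effects on the trait; 0 gives full mediation.
#' @param fracSexBiased Fraction of SNP-gene pairs flagged sex-biased,
#'   in `[0, 1]`.
#' @param pleiotropy When `TRUE`, the SNPs of every odd-numbered gene also
#'   affect the following gene at half magnitude, giving shared
#'   instruments that exercise the multivariable MR path.
#' @param seed Integer seed controlling every draw.
#' @return A validated list of class `"SimParams"`.
#' @examples
#' p <- simParams(nF = 100, nM = 100, nGenes = 2, seed = 1)
#' print(p)
#' @export
simParams <- function(nF = 1928, nM = 1519, nGenes = 10, nSnpsPerGene = 5,
                      mafRange = c(0.05, 0.5), betaF = 0.4, betaM = 0.2,
                      sdExprF = 1, sdExprM = 1, alphaF = 0.1, alphaM = 0.1,
                      directSnpEffectSd = 0, fracSexBiased = 0.5,
                      pleiotropy = FALSE, seed = 1L) {
  stopifnot(nF >= 2, nM >= 2, nGenes >= 1, nSnpsPerGene >= 1)
  if (length(mafRange) != 2L || mafRange[1L] <= 0 || mafRange[2L] > 0.5 ||
      mafRange[1L] > mafRange[2L])
    stop("mafRange must be an interval within (0, 0.5]")
  if (any(c(sdExprF, sdExprM) <= 0))
    stop("expression noise standard deviations must be positive")
  if (directSnpEffectSd < 0) stop("directSnpEffectSd must be >= 0")
  if (fracSexBiased < 0 || fracSexBiased > 1)
    stop("fracSexBiased must lie in [0, 1]")
  p <- list(nF = as.integer(nF), nM = as.integer(nM),
            nGenes = as.integer(nGenes),
            nSnpsPerGene = as.integer(nSnpsPerGene),
            mafRange = as.numeric(mafRange),
            betaF = betaF, betaM = betaM,
            sdExprF = sdExprF, sdExprM = sdExprM,
            alphaF = alphaF, alphaM = alphaM,
            directSnpEffectSd = directSnpEffectSd,
            fracSexBiased = fracSexBiased,
            pleiotropy = isTRUE(pleiotropy), seed = as.integer(seed))
  class(p) <- "SimParams"
  p
}

#' @export
print.SimParams <- function(x, ...) {
  cat("Simulation scenario:\n")
  cat(sprintf("  %d F + %d M individuals; %d genes x %d cis SNPs\n",
              x$nF, x$nM, x$nGenes, x$nSnpsPerGene))
  cat(sprintf("  MAF ~ U(%.2f, %.2f); betaF=%s betaM=%s (%.0f%% of pairs sex-biased)\n",
              x$mafRange[1L], x$mafRange[2L],
              paste(signif(x$betaF, 3), collapse = ","),
              paste(signif(x$betaM, 3), collapse = ","),
              100 * x$fracSexBiased))
  cat(sprintf("  expr noise sd F=%s M=%s; alphaF=%s alphaM=%s; direct sd=%.3g; seed=%d\n",
              paste(signif(x$sdExprF, 3), collapse = ","),
              paste(signif(x$sdExprM, 3), collapse = ","),
              paste(signif(x$alphaF, 3), collapse = ","),
              paste(signif(x$alphaM, 3), collapse = ","),
              x$directSnpEffectSd, x$seed))
  invisible(x)
}

.gene_ids <- function(p) sprintf("g%03d", seq_len(p$nGenes))
.snp_ids <- function(p) {
  as.vector(vapply(seq_len(p$nGenes), function(g)
    sprintf("g%03d_s%02d", g, seq_len(p$nSnpsPerGene)),
    character(p$nSnpsPerGene)))
}
# Loci 3 Mb apart, at most 80 per synthetic chromosome so coordinates
# stay within a realistic chromosome length.
.GENES_PER_CHROM <- 80L
.gene_layout <- function(p) {
  g <- seq_len(p$nGenes)
  data.frame(gene_id = .gene_ids(p),
             chrom = as.character((g - 1L) %/% .GENES_PER_CHROM + 1L),
             center = 3e6 * ((g - 1L) %% .GENES_PER_CHROM + 1L))
}
.snp_positions <- function(p) {
  off <- if (p$nSnpsPerGene == 1L) 0 else
    round(seq(-9e5, 9e5, length.out = p$nSnpsPerGene))
  as.vector(outer(off, .gene_layout(p)$center, `+`))
}

#' Ground truth for a simulation scenario
#'
#' Draws the sex-biased pair flags, per-pair effect sizes, per-gene causal
#' effects, and direct SNP effects implied by a [simParams()] scenario.
#' The returned object is the reference against which recovery of
#' sex-biased pairs, eGenes and causal effects is scored.
#'
#' @param params A `"SimParams"` object.
#' @return List of class `"SimTruth"` with elements `eqtl` (one row per
#'   SNP-gene pair: `snp_id`, `gene_id`, `beta_f`, `beta_m`,
#'   `sex_biased`), `gene` (`gene_id`, `alpha_f`, `alpha_m`) and `snp`
#'   (`snp_id`, `delta`, the direct trait effect).
#' @export
buildTruth <- function(params) {
  stopifnot(inherits(params, "SimParams"))
  p <- params
  set.seed(p$seed)
  snp_id <- .snp_ids(p)
  gene_id <- rep(.gene_ids(p), each = p$nSnpsPerGene)
  n_pairs <- length(snp_id)
  biased <- runif(n_pairs) < p$fracSexBiased
  beta_f_all <- rep_len(p$betaF, n_pairs)
  beta_m_all <- rep_len(p$betaM, n_pairs)
  beta_m <- beta_m_all
  beta_f <- ifelse(biased, beta_f_all, beta_m_all)
  eqtl <- data.frame(snp_id = snp_id, gene_id = gene_id,
                     beta_f = beta_f, beta_m = beta_m,
                     sex_biased = biased & (beta_f != beta_m))
  if (p$pleiotropy && p$nGenes >= 2L) {
    odd <- seq(1L, p$nGenes - 1L, by = 2L)
    extra <- do.call(rbind, lapply(odd, function(g) {
      rows <- eqtl$gene_id == sprintf("g%03d", g)
      data.frame(snp_id = eqtl$snp_id[rows],
                 gene_id = sprintf("g%03d", g + 1L),
                 beta_f = eqtl$beta_f[rows] / 2,
                 beta_m = eqtl$beta_m[rows] / 2,
                 sex_biased = eqtl$sex_biased[rows])
    }))
    eqtl <- rbind(eqtl, extra)
  }
  gene <- data.frame(gene_id = .gene_ids(p),
                     alpha_f = rep_len(p$alphaF, p$nGenes),
                     alpha_m = rep_len(p$alphaM, p$nGenes))
  delta <- if (p$directSnpEffectSd > 0)
    rnorm(n_pairs, 0, p$directSnpEffectSd) else rep(0, n_pairs)
  snp <- data.frame(snp_id = snp_id, delta = delta)
  structure(list(eqtl = eqtl, gene = gene, snp = snp), class = "SimTruth")
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Draws per-SNP minor allele frequencies uniformly from the scenario's
#' `mafRange` and dosages as `Binomial(2, maf)` independently across
#' individuals, so Hardy-Weinberg equilibrium holds in expectation.
#' SNPs are laid out on one chromosome with each gene's SNPs within
#' +/- 0.9 Mb of its center and 3 Mb between gene centers, so cis windows
#' of neighbouring genes never share SNPs.
#'
#' @param params A `"SimParams"` object.
#' @return A [GenotypeExperiment-class] with sex labels in `colData`
#'   (females first, then males).
#' @export
simulateGenotypes <- function(params) {
  stopifnot(inherits(params, "SimParams"))
  p <- params
  n <- p$nF + p$nM
  if (n < 2L) stop("need at least 2 individuals")
  set.seed(p$seed + 1L)
  snp_id <- .snp_ids(p)
  m <- length(snp_id)
  maf <- runif(m, p$mafRange[1L], p$mafRange[2L])
  dos <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), nrow = n, ncol = m)
  rownames(dos) <- sprintf("ind%05d", seq_len(n))
  sex <- rep(c("F", "M"), c(p$nF, p$nM))
  layout <- .gene_layout(p)
  GenotypeExperiment(dos, snpId = snp_id,
                     chrom = rep(layout$chrom, each = p$nSnpsPerGene),
                     pos = .snp_positions(p), maf = pmin(maf, 1 - maf),
                     sex = sex)
}

# Standardize dosage columns to mean 0, variance ~1 using the estimated
# allele frequency: (d - 2*p_hat)/sqrt(2*p_hat*(1-p_hat)).
.std_dosage <- function(X) {
  p_hat <- colMeans(X, na.rm = TRUE) / 2
  denom <- sqrt(2 * p_hat * (1 - p_hat))
  denom[denom == 0] <- NA_real_
  sweep(sweep(X, 2L, 2 * p_hat, `-`), 2L, denom, `/`)
}

# Standardize columns to mean 0, sample sd 1 (for regression-scale betas).
.std_cols <- function(X) {
  X <- sweep(X, 2L, colMeans(X, na.rm = TRUE), `-`)
  s <- apply(X, 2L, sd, na.rm = TRUE)
  s[s == 0] <- NA_real_
  sweep(X, 2L, s, `/`)
}

#' Simulate expression under per-sex eQTL effects
#'
#' For an individual of sex `s`, the expression of gene `g` is the sum of
#' `beta[s, snp, g] * std(dosage)` over its cis SNPs plus Gaussian noise
#' with the scenario's per-sex, per-gene standard deviation. Dosages are
#' standardized by the estimated allele frequency so the injected effects
#' are on the standardized scale.
#'
#' @param genotypes A [GenotypeExperiment-class] from
#'   [simulateGenotypes()].
#' @param truth A `"SimTruth"` from [buildTruth()].
#' @param params The matching `"SimParams"`.
#' @return An [ExpressionExperiment-class] with gene center positions and
#'   sex labels.
#' @export
simulateExpression <- function(genotypes, truth, params) {
  stopifnot(inherits(params, "SimParams"), inherits(truth, "SimTruth"))
  p <- params
  X <- dosageMatrix(genotypes)
  sex <- sexLabels(genotypes)
  n <- nrow(X)
  set.seed(p$seed + 2L)
  Xs <- .std_dosage(X)
  Xs[is.na(Xs)] <- 0
  genes <- .gene_ids(p)
  B_f <- B_m <- matrix(0, ncol(X), length(genes),
                       dimnames = list(colnames(X), genes))
  idx <- cbind(match(truth$eqtl$snp_id, colnames(X)),
               match(truth$eqtl$gene_id, genes))
  B_f[idx] <- truth$eqtl$beta_f
  B_m[idx] <- truth$eqtl$beta_m
  E <- matrix(0, n, length(genes), dimnames = list(rownames(X), genes))
  sd_f <- rep_len(p$sdExprF, length(genes))
  sd_m <- rep_len(p$sdExprM, length(genes))
  fe <- sex == "F"
  E[fe, ] <- Xs[fe, , drop = FALSE] %*% B_f +
    matrix(rnorm(sum(fe) * length(genes), 0, rep(sd_f, each = sum(fe))),
           sum(fe), length(genes))
  E[!fe, ] <- Xs[!fe, , drop = FALSE] %*% B_m +
    matrix(rnorm(sum(!fe) * length(genes), 0, rep(sd_m, each = sum(!fe))),
           sum(!fe), length(genes))
  layout <- .gene_layout(p)
  ExpressionExperiment(E, geneId = genes, chrom = layout$chrom,
                       centerPos = layout$center, sex = sex)
}

#' Simulate a trait under the mediation model
#'
#' The trait of individual `i` of sex `s` is
#' `sum_g alpha[s, g] * expr[i, g] + sum_snp delta[snp] * std(dosage) +
#' e_i` with `e ~ N(0, 1)`. With `directSnpEffectSd = 0` the SNP-trait
#' association is fully mediated by expression, so the standardized
#' SNP-trait effect equals `alpha * beta_eQTL` in expectation (up to the
#' trait's total standard deviation).
#'
#' @inheritParams simulateExpression
#' @param expression An [ExpressionExperiment-class] from
#'   [simulateExpression()].
#' @return Named numeric vector of trait values, one per individual.
#' @export
simulateTrait <- function(expression, genotypes, truth, params) {
  stopifnot(inherits(params, "SimParams"), inherits(truth, "SimTruth"))
  p <- params
  E <- exprMatrix(expression)
  X <- dosageMatrix(genotypes)
  sex <- sexLabels(expression)
  stopifnot(nrow(E) == nrow(X))
  set.seed(p$seed + 3L)
  genes <- colnames(E)
  a_f <- truth$gene$alpha_f[match(genes, truth$gene$gene_id)]
  a_m <- truth$gene$alpha_m[match(genes, truth$gene$gene_id)]
  y <- numeric(nrow(E))
  fe <- sex == "F"
  y[fe] <- E[fe, , drop = FALSE] %*% a_f
  y[!fe] <- E[!fe, , drop = FALSE] %*% a_m
  if (any(truth$snp$delta != 0)) {
    Xs <- .std_dosage(X)
    Xs[is.na(Xs)] <- 0
    delta <- truth$snp$delta[match(colnames(X), truth$snp$snp_id)]
    delta[is.na(delta)] <- 0
    y <- y + as.vector(Xs %*% delta)
  }
  y <- y + rnorm(length(y))
  names(y) <- rownames(E)
  y
}

#' Per-stratum single-SNP association summary statistics
#'
#' Runs, for every SNP, the simple linear regression of the standardized
#' outcome on the standardized dosage, separately per sex stratum (or on
#' all individuals when `stratify = FALSE`), and returns the standardized
#' slope (equal to the Pearson correlation), its standard error, the
#' per-stratum sample size and a two-sided p-value from the t
#' distribution with `n - 2` degrees of freedom. This is the generator of
#' sex-stratified GWAS-style summary statistics.
#'
#' Strata with fewer than 3 complete observations are skipped with a
#' warning; SNPs with no dosage variance in a stratum yield `NA` rows,
#' dropped with a warning.
#'
#' @param genotypes A [GenotypeExperiment-class].
#' @param outcome Numeric outcome vector (a trait, or one expression
#'   column), one value per individual.
#' @param sex Per-individual `"F"`/`"M"` labels; defaults to the labels
#'   stored in `genotypes`.
#' @param stratify Compute per-sex tables (`TRUE`) or a single combined
#'   table (`FALSE`).
#' @param unitId Value for the `unit_id` column (trait or gene name).
#' @return Summary-statistic `data.frame` in the [readSummaryStats()]
#'   layout, with explicit standard errors
#'   (`attr(,"standardized") = FALSE`).
#' @export
computeSummaryStats <- function(genotypes, outcome,
                                sex = sexLabels(genotypes),
                                stratify = TRUE, unitId = "trait") {
  X <- dosageMatrix(genotypes)
  stopifnot(length(outcome) == nrow(X))
  strata <- if (stratify) list(F = sex == "F", M = sex == "M")
            else list(combined = rep(TRUE, nrow(X)))
  out <- lapply(names(strata), function(sn) {
    keep <- strata[[sn]] & !is.na(outcome)
    if (sum(keep) < 3L) {
      warning(sprintf("stratum %s has fewer than 3 individuals; skipped", sn))
      return(NULL)
    }
    .marginal_regression(X[keep, , drop = FALSE], outcome[keep], sn, unitId)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(snp_id = character(), unit_id = character(),
                      stratum = character(), beta = numeric(),
                      se = numeric(), n = integer(), p = numeric())
  attr(res, "standardized") <- FALSE
  res
}

# Vectorized standardized simple regression of y on each column of X.
.marginal_regression <- function(X, y, stratum, unitId) {
  n_obs <- colSums(!is.na(X))
  ys <- (y - mean(y)) / sd(y)
  r <- suppressWarnings(as.vector(stats::cor(X, ys, use = "pairwise.complete.obs")))
  se <- sqrt(pmax(1 - r^2, 0) / (n_obs - 2))
  tt <- ifelse(se > 0, r / se, sign(r) * Inf)
  p <- 2 * pt(-abs(tt), df = n_obs - 2)
  p[p == 0] <- .Machine$double.xmin  # keep p in (0, 1]
  res <- data.frame(snp_id = colnames(X), unit_id = unitId,
                    stratum = stratum, beta = r, se = se,
                    n = as.integer(n_obs), p = p, row.names = NULL)
  drop <- !is.finite(res$beta)  # constant dosage: correlation undefined
  if (any(drop)) {
    warning(sprintf("%d SNP(s) without dosage variance in stratum %s dropped",
                    sum(drop), stratum))
    res <- res[!drop, , drop = FALSE]
  }
  res
}
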