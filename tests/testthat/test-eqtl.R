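make_geno <- function(pos, chrom = rep("1", length(pos)), n = 6) {
  set.seed(1)
  d <- matrix(rbinom(n * length(pos), 2, 0.4), n, length(pos))
  GenotypeExperiment(d, sprintf("s%d", seq_along(pos)), chrom, pos,
                     sex = rep(c("F", "M"), length.out = n))
}

test_that("cis pair selection uses an inclusive same-chromosome 1 Mb window", {
  g <- make_geno(pos = 2e6)
  e <- ExpressionExperiment(matrix(rnorm(18), 6, 3), c("gA", "gB", "gC"),
                            c("1", "1", "2"), c(1e6, 3000001, 2e6))
  pairs <- selectCisPairs(g, e)
  expect_equal(pairs$gene_id, "gA")  # boundary at exactly 1 Mb included
  # other chromosome excluded even at distance zero; 1 bp beyond excluded

  g2 <- make_geno(pos = c(1e6, 1.5e6, 2e6))
  e2 <- ExpressionExperiment(matrix(rnorm(12), 6, 2), c("g1", "g2"),
                             c("1", "1"), c(1.2e6, 1.8e6))
  expect_equal(nrow(selectCisPairs(g2, e2)), 6L)  # full cartesian set
})

test_that("PC residualization removes retained PCs and drops genetic PCs", {
  set.seed(21)
  n <- 60
  d <- matrix(rbinom(n * 3, 2, 0.4), n, 3)
  g <- GenotypeExperiment(d, c("s1", "s2", "s3"), rep("1", 3),
                          c(1e6, 2e6, 3e6))
  # gene 1..4 structured around the dosage of s1 (a genetic PC), plus noise
  E <- cbind(outer(d[, 1], c(2, -1, 1.5, 0.5)), matrix(rnorm(n * 6), n, 6))
  e <- ExpressionExperiment(E, sprintf("g%d", 1:10), rep("1", 10),
                            3e6 * (1:10))
  out <- residualizePCs(e, g, nPcs = 5, assocPThreshold = 1e-12)
  rep <- S4Vectors::metadata(out)$pc_report
  expect_true("PC1" %in% rep$dropped)  # dosage-dominated component dropped
  expect_lt(rep$min_assoc_p["PC1"], 1e-12)
  # residuals orthogonal to every retained PC
  pcs <- prcomp(exprMatrix(e), center = TRUE)$x[, 1:5]
  keep <- pcs[, rep$retained, drop = FALSE]
  if (ncol(keep))
    expect_lt(max(abs(cor(exprMatrix(out), keep))), 1e-10)
  expect_error(residualizePCs(e, g, nPcs = 0), "positive")
})

test_that("rank-correlation mapping is exact, antisymmetric and monotone-invariant", {
  set.seed(31)
  n <- 40
  d <- matrix(rbinom(n, 2, 0.5), n, 1)
  g <- GenotypeExperiment(d, "s1", "1", 1e6, sex = rep(c("F", "M"), n / 2))
  pairs <- data.frame(snp_id = "s1", gene_id = "g1")

  # strictly increasing function of dosage shares its tie structure: rho = 1
  e1 <- ExpressionExperiment(matrix(exp(d[, 1]), n, 1), "g1", "1", 1e6,
                             sex = sexLabels(g))
  expect_equal(mapEqtls(g, e1, pairs, "combined")$beta, 1)

  y <- rnorm(n) + 0.5 * d[, 1]
  eY <- ExpressionExperiment(matrix(y, n, 1), "g1", "1", 1e6,
                             sex = sexLabels(g))
  base <- mapEqtls(g, eY, pairs, "combined")
  # invariant to strictly monotone transforms, sign flips on negation
  eT <- ExpressionExperiment(matrix(exp(2 * y), n, 1), "g1", "1", 1e6,
                             sex = sexLabels(g))
  expect_equal(mapEqtls(g, eT, pairs, "combined")$beta, base$beta)
  eN <- ExpressionExperiment(matrix(-y, n, 1), "g1", "1", 1e6,
                             sex = sexLabels(g))
  neg <- mapEqtls(g, eN, pairs, "combined")
  expect_equal(neg$beta, -base$beta)
  expect_equal(neg$p, base$p)
})

test_that("mapping p-values are uniform when expression is independent of dosage", {
  p <- simParams(nF = 150, nM = 150, nGenes = 200, nSnpsPerGene = 5,
                 betaF = 0, betaM = 0, seed = 32)
  g <- simulateGenotypes(p)
  e <- simulateExpression(g, buildTruth(p), p)
  tab <- mapEqtls(g, e, selectCisPairs(g, e), "combined")
  expect_equal(nrow(tab), 1000L)
  expect_gt(stats::ks.test(tab$p, "punif")$p.value, 0.01)
})

test_that("pairwise-complete cases are used and tiny pairs are skipped", {
  n <- 30
  set.seed(41)
  d <- matrix(rbinom(2 * n, 2, 0.5), n, 2)
  d[1:5, 1] <- NA
  g <- GenotypeExperiment(d, c("s1", "s2"), c("1", "1"), c(1e6, 1.5e6),
                          sex = rep(c("F", "M"), n / 2))
  y <- rnorm(n)
  e <- ExpressionExperiment(matrix(y, n, 1), "g1", "1", 1e6,
                            sex = sexLabels(g))
  pairs <- data.frame(snp_id = c("s1", "s2"), gene_id = "g1")
  tab <- mapEqtls(g, e, pairs, "combined")
  expect_equal(tab$n, c(25L, 30L))
  ok <- !is.na(d[, 1])
  expect_equal(tab$beta[1], cor(d[ok, 1], y[ok], method = "spearman"),
               tolerance = 1e-12)

  d2 <- d; d2[3:n, 2] <- NA  # 2 complete cases only
  g2 <- GenotypeExperiment(d2, c("s1", "s2"), c("1", "1"), c(1e6, 1.5e6),
                           sex = sexLabels(g))
  expect_warning(tab2 <- mapEqtls(g2, e, pairs, "combined"),
                 "fewer than 3")
  expect_equal(tab2$snp_id, "s1")
})

test_that("meta-analysis combines strata by sample-size weighting", {
  tF <- data.frame(snp_id = "s1", unit_id = "g1", stratum = "F",
                   beta = 0.3, se = NA, n = 1928L, p = 0.001)
  tM <- data.frame(snp_id = "s1", unit_id = "g1", stratum = "M",
                   beta = 0.1, se = NA, n = 1519L, p = 0.2)
  mc <- metaAnalyze(tF, tM)
  expect_equal(mc$beta, (1928 * 0.3 + 1519 * 0.1) / 3447, tolerance = 1e-12)
  expect_equal(mc$beta, 0.2118654, tolerance = 1e-7)
  expect_equal(mc$n, 3447L)

  # consensus: equal effects pass through; doubling n inflates z by sqrt(2)
  same <- metaAnalyze(tF, transform(tF, stratum = "M"))
  expect_equal(same$beta, 0.3)
  zF <- tF$beta * sqrt(tF$n)
  expect_equal(same$beta * sqrt(same$n), sqrt(2) * zF)

  expect_error(metaAnalyze(tF, transform(tM, snp_id = "s2")), "only one")
})

test_that("both strata recover a shared standardized effect without bias", {
  errs <- sapply(1:60, function(s) {
    p <- simParams(nF = 1500, nM = 1500, nGenes = 1, nSnpsPerGene = 1,
                   betaF = 0.2, betaM = 0.2, fracSexBiased = 0, seed = 400 + s)
    g <- simulateGenotypes(p)
    e <- simulateExpression(g, buildTruth(p), p)
    tab <- rbind(mapEqtls(g, e, data.frame(snp_id = colnames(dosageMatrix(g)),
                                           gene_id = "g001"), "F"),
                 mapEqtls(g, e, data.frame(snp_id = colnames(dosageMatrix(g)),
                                           gene_id = "g001"), "M"))
    tab$beta - 0.2
  })
  # rank-correlation estimand sits slightly below the injected linear
  # effect (noise attenuation); typical recovery error stays within 0.05
  expect_lt(abs(mean(errs)), 0.03)
  expect_lt(median(abs(errs)), 0.05)
  expect_gt(mean(abs(errs) < 0.05), 0.80)
})
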