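test_that("eQTL-difference statistic matches direct arithmetic and is antisymmetric", {
  r <- eqtlDiffTest(0.5, 0.3, 1928, 1519)
  expect_equal(r$statistic, 0.2 / sqrt(1 / 1928 + 1 / 1519), tolerance = 1e-12)
  expect_equal(round(r$statistic, 3), 5.830)
  expect_equal(eqtlDiffTest(0.2, 0.2, 100, 100)$p_diff, 1)

  sw <- eqtlDiffTest(0.3, 0.5, 1519, 1928)
  expect_equal(sw$statistic, -r$statistic)
  expect_equal(sw$p_diff, r$p_diff)
  expect_error(eqtlDiffTest(0.1, 0.2, 0, 10), "positive")
})

test_that("GWAS-difference statistic matches the normal-tail oracle", {
  r <- gwasDiffTest(0.10, 0.01, 0.06, 0.01)
  expect_equal(r$statistic, 0.04 / sqrt(2e-4), tolerance = 1e-12)
  expect_equal(signif(r$p_diff, 3), 4.68e-3)
  expect_equal(gwasDiffTest(0.1, 0.02, 0.1, 0.02)$p_diff, 1)
  # doubling both standard errors halves the statistic
  expect_equal(gwasDiffTest(0.1, 0.02, 0.06, 0.02)$statistic,
               r$statistic / 2)
  expect_error(gwasDiffTest(0.1, 0, 0.2, 0.1), "positive")
})

test_that("expression mean test uses standard errors of the mean", {
  s <- data.frame(gene_id = "g1", mean_F = 1.0, sem_F = 0.1,
                  mean_M = 0.7, sem_M = 0.1)
  r <- deMeanTest(s)
  expect_equal(round(r$statistic, 3), 2.121)
  s0 <- transform(s, mean_M = 1.0)
  expect_equal(deMeanTest(s0)$statistic, 0)
  swapped <- data.frame(gene_id = "g1", mean_F = 0.7, sem_F = 0.1,
                        mean_M = 1.0, sem_M = 0.1)
  expect_equal(deMeanTest(swapped)$statistic, -r$statistic)
})

test_that("variance F-test agrees with var.test on random samples", {
  set.seed(101)
  for (i in 1:100) {
    nx <- sample(5:60, 1); ny <- sample(5:60, 1)
    x <- rnorm(nx, sd = runif(1, 0.5, 3)); y <- rnorm(ny, sd = runif(1, 0.5, 3))
    mine <- varianceFTest(var(x), var(y), nx, ny)
    ref <- var.test(x, y)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(mine$p_diff, ref$p.value, tolerance = 1e-8)
  }
  expect_equal(varianceFTest(1, 1, 50, 50)$p_diff, 1)
  # reciprocal inputs with swapped n give reciprocal F, identical p
  a <- varianceFTest(2, 1, 101, 101)
  b <- varianceFTest(1, 2, 101, 101)
  expect_equal(a$statistic, 1 / b$statistic)
  expect_equal(a$p_diff, b$p_diff)
  expect_error(varianceFTest(1, 0, 10, 10), "positive")
})

test_that("the printed-df toggle changes the reference distribution", {
  std <- varianceFTest(2, 1, 101, 101)
  printed <- varianceFTest(2, 1, 101, 101, dfAsPrinted = TRUE)
  expect_equal(printed$p_diff,
               2 * pf(2, 101, 101, lower.tail = FALSE), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(std$p_diff, printed$p_diff)))
})

test_that("BH selection matches brute-force step-up enumeration", {
  # step-up: the largest rank k with p_(k) <= k*q/m wins, and every
  # smaller p is selected with it (here 0.041 <= 4*0.05/4, so all four)
  r <- bhFdr(c(0.001, 0.008, 0.039, 0.041), 0.05)
  expect_equal(r$selected, rep(TRUE, 4))
  expect_equal(r$pThreshold, 0.041)
  ref <- bh_brute_force(c(0.001, 0.008, 0.039, 0.041), 0.05)
  expect_identical(r$selected, ref$selected)
  # without the rescuing fourth p-value only the first two survive
  r2 <- bhFdr(c(0.001, 0.008, 0.039, 0.9), 0.05)
  expect_equal(r2$selected, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$pThreshold, 0.008)
  expect_false(any(bhFdr(rep(1, 10))$selected))
  expect_true(all(bhFdr(rep(0.004, 10), 0.05)$selected))

  set.seed(102)
  for (i in 1:100) {
    m <- sample(3:200, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    mine <- bhFdr(p, q)
    ref <- bh_brute_force(p, q)
    expect_identical(mine$selected, ref$selected)
    expect_equal(mine$pThreshold, ref$threshold, tolerance = 1e-12)
    expect_equal(mine$q, p.adjust(p, "BH"))  # q consistent with selection
    expect_true(all(mine$q >= p - 1e-12))
  }
})

test_that("lead eQTL choice takes the strongest difference with documented ties", {
  d <- data.frame(snp_id = c("b", "a", "c"), unit_id = "g1",
                  statistic = c(2.1, -5.8, 3.3), p_diff = c(0.03, 1e-8, 0.001))
  expect_equal(pickLeadEqtl(d)$snp_id, "a")  # max |t| wins
  tie <- data.frame(snp_id = c("z", "k"), unit_id = "g1",
                    statistic = c(2, -2), p_diff = c(0.05, 0.05))
  expect_equal(pickLeadEqtl(tie)$snp_id, "k")  # lexicographic tie-break
  single <- d[1, ]
  expect_equal(pickLeadEqtl(single)$snp_id, "b")
  two <- rbind(d, data.frame(snp_id = "d", unit_id = "g2",
                             statistic = 1, p_diff = 0.3))
  expect_equal(pickLeadEqtl(two)$unit_id, c("g1", "g2"))
})

test_that("hypergeometric enrichment matches pmf summation", {
  r <- hypergeomEnrichment(3, 5, 10, 100)
  expect_equal(r$p, hyper_tail_sum(3, 5, 10, 100), tolerance = 1e-12)
  set.seed(103)
  for (i in 1:100) {
    nU <- sample(20:500, 1)
    nA <- sample(1:(nU - 1), 1); nB <- sample(1:(nU - 1), 1)
    lo <- max(0, nA + nB - nU)
    k <- sample(lo:min(nA, nB), 1)
    expect_equal(hypergeomEnrichment(k, nA, nB, nU)$p,
                 hyper_tail_sum(k, nA, nB, nU), tolerance = 1e-8)
  }
  sat <- hypergeomEnrichment(7, 7, 7, 7)  # degenerate saturation
  expect_equal(sat$p, 1)
  expect_equal(sat$odds_ratio, Inf)
  expect_gt(hypergeomEnrichment(0, 3, 3, 1000)$p, 0.97)
  expect_error(hypergeomEnrichment(5, 3, 10, 100), "impossible")
})

test_that("rank-sum test matches exhaustive enumeration at small n", {
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))$p, 0.1,
               tolerance = 1e-12)
  set.seed(104)
  for (i in 1:40) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    expect_equal(wilcoxonRankSum(x, y)$p, wilcoxon_enumerate(x, y),
                 tolerance = 1e-8)
  }
  expect_gt(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))$p, 0.99)
  # rank test: invariant to common strictly monotone transforms
  x <- rnorm(30); y <- rnorm(25, 0.5)
  expect_equal(wilcoxonRankSum(exp(x), exp(y))$p, wilcoxonRankSum(x, y)$p)
  expect_error(wilcoxonRankSum(numeric(), 1), "non-empty")
})

test_that("Levene's test matches the reference implementation", {
  skip_if_not_installed("car")
  set.seed(105)
  for (i in 1:100) {
    nx <- sample(3:40, 1); ny <- sample(3:40, 1)
    x <- rnorm(nx, sd = runif(1, 0.5, 3)); y <- rnorm(ny)
    mine <- leveneTest(x, y)
    grp <- factor(rep(c("F", "M"), c(nx, ny)))
    ref <- car::leveneTest(c(x, y), grp, center = "mean")
    expect_equal(mine$statistic, ref$`F value`[1], tolerance = 1e-8)
    expect_equal(mine$p, ref$`Pr(>F)`[1], tolerance = 1e-8)
  }
  expect_equal(leveneTest(c(1, 1, 1), c(1, 1))$statistic, 0)
  # location-free: adding a constant to one group changes nothing
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(leveneTest(x + 100, y)$statistic, leveneTest(x, y)$statistic)
  expect_error(leveneTest(1, c(1, 2)), "at least 2")
})

test_that("effective test count follows the eigenvalue rule", {
  expect_equal(effectiveTests(diag(39)), 39L)
  expect_equal(effectiveTests(matrix(1, 10, 10)), 1L)
  blk <- kronecker(diag(5), matrix(1, 4, 4))  # 5 independent blocks of 4
  expect_equal(effectiveTests(blk), 5L)
  expect_error(effectiveTests(matrix(c(1, 0.5, 0.2, 1), 2, 2)), "symmetric")
})

test_that("difference scan over tables dispatches on the variance convention", {
  tF <- data.frame(snp_id = c("s1", "s2"), unit_id = "g1", stratum = "F",
                   beta = c(0.5, 0.2), se = NA_real_, n = 1928L,
                   p = c(1e-8, 0.01))
  tM <- transform(tF, stratum = "M", beta = c(0.3, 0.2), n = 1519L)
  attr(tF, "standardized") <- attr(tM, "standardized") <- TRUE
  d <- diffTestTables(tF, tM)
  expect_equal(d$statistic[1], 0.2 / sqrt(1 / 1928 + 1 / 1519),
               tolerance = 1e-12)
  expect_equal(d$statistic[2], 0)
  expect_true(all(d$q >= d$p_diff - 1e-12))

  gF <- data.frame(snp_id = "s1", unit_id = "bmi", stratum = "F",
                   beta = 0.10, se = 0.01, n = 190000L, p = 1e-20)
  gM <- transform(gF, stratum = "M", beta = 0.06, n = 170000L)
  attr(gF, "standardized") <- attr(gM, "standardized") <- FALSE
  d2 <- diffTestTables(gF, gM)
  expect_equal(d2$statistic, 0.04 / sqrt(2e-4), tolerance = 1e-12)
})
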