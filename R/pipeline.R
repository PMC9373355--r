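#' Bonferroni screen of lead eQTLs against sex-stratified GWAS effects
#'
#' For every lead sex-biased eQTL and every trait present in the GWAS
#' tables, tests whether the SNP's trait effect differs between the
#' sexes ([gwasDiffTest()]). Significance is declared at the Bonferroni
#' threshold `level / (mEff * nEgenes)`, where `mEff` is the effective
#' number of independent phenotypes (see [effectiveTests()]) and
#' `nEgenes` the number of eGenes screened. Lead SNPs missing from a
#' trait's tables are skipped and listed in the result's
#' `"missing"` attribute.
#'
#' @param leadTable `data.frame` of lead eQTLs with at least `snp_id`
#'   and a gene column (`unit_id`).
#' @param gwasTableF,gwasTableM GWAS summary-statistic tables for the
#'   two sexes; `unit_id` identifies the trait.
#' @param mEff Effective number of independent phenotypes (default: the
#'   number of distinct traits in the tables).
#' @param level Family-wise error level (default 0.05).
#' @param nEgenes Number of eGenes screened (default: distinct genes in
#'   `leadTable`).
#' @return `data.frame` with `snp_id`, `gene_id`, `trait`, `beta_F`,
#'   `beta_M`, `delta`, `statistic`, `p_diff`, `significant`;
#'   attributes `"threshold"` and `"missing"`.
#' @export
gwasContrastScreen <- function(leadTable, gwasTableF, gwasTableM,
                               mEff = NULL, level = 0.05, nEgenes = NULL) {
  traits <- union(unique(gwasTableF$unit_id), unique(gwasTableM$unit_id))
  nEgenes <- nEgenes %||% length(unique(leadTable$unit_id))
  mEff <- mEff %||% length(traits)
  threshold <- level / (mEff * nEgenes)
  if (!length(traits) || !nrow(leadTable)) {
    warning("no GWAS tables or no lead eQTLs supplied; empty screen")
    out <- data.frame(snp_id = character(), gene_id = character(),
                      trait = character(), beta_F = numeric(),
                      beta_M = numeric(), delta = numeric(),
                      statistic = numeric(), p_diff = numeric(),
                      significant = logical())
    attr(out, "threshold") <- threshold
    attr(out, "missing") <- character()
    return(out)
  }
  grid <- expand.grid(i = seq_len(nrow(leadTable)), trait = traits,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keyF <- paste(gwasTableF$snp_id, gwasTableF$unit_id)
  keyM <- paste(gwasTableM$snp_id, gwasTableM$unit_id)
  want <- paste(leadTable$snp_id[grid$i], grid$trait)
  iF <- match(want, keyF)
  iM <- match(want, keyM)
  found <- !is.na(iF) & !is.na(iM)
  missing <- unique(want[!found])
  res <- gwasDiffTest(gwasTableF$beta[iF[found]], gwasTableF$se[iF[found]],
                      gwasTableM$beta[iM[found]], gwasTableM$se[iM[found]])
  gene_col <- if ("unit_id" %in% colnames(leadTable)) "unit_id" else "gene_id"
  out <- data.frame(snp_id = leadTable$snp_id[grid$i[found]],
                    gene_id = leadTable[[gene_col]][grid$i[found]],
                    trait = grid$trait[found],
                    beta_F = gwasTableF$beta[iF[found]],
                    beta_M = gwasTableM$beta[iM[found]],
                    res, significant = res$p_diff < threshold,
                    row.names = NULL)
  attr(out, "threshold") <- threshold
  attr(out, "missing") <- missing
  out
}

.default_config <- function() {
  list(sim = list(), nPcs = 0L, pcAssocThreshold = 1e-12,
       window = 1e6, fdrLevel = 0.05, pInst = 1e-3, r2Prune = 0.1,
       mEff = 1L, crit = 5.43, powerNGwasF = 190000, powerNGwasM = 170000,
       seed = 1L)
}

#' Run the full sex-dimorphism analysis pipeline on synthetic data
#'
#' Executes the stages in fixed order: simulate genotypes, expression and
#' trait under the configured scenario; optionally residualize expression
#' on genetics-free principal components; select cis pairs; map eQTLs per
#' sex and meta-analyze; test every pair for a sex difference with BH-FDR
#' selection; pick lead eQTLs of the significant eGenes; compute
#' sex-stratified GWAS summary statistics for the trait and screen the
#' lead SNPs at the Bonferroni threshold; run TWMR per sex and contrast
#' the causal effects; evaluate analytic power and required sample size
#' for each significant eGene's lead difference. All intermediate tables
#' can be written to `outDir`, together with a machine-readable JSON run
#' report. Identical `config` (including the seed) reproduces the run
#' exactly; only the stage timings differ.
#'
#' @param config Named list or path to a YAML file. Recognized keys:
#'   `sim` (arguments of [simParams()]), `seed`, `nPcs`,
#'   `pcAssocThreshold`, `window`, `fdrLevel`, `pInst`, `r2Prune`,
#'   `mEff`, `crit`, `powerNGwasF`, `powerNGwasM`. Missing keys take the
#'   defaults shown in the vignette.
#' @param outDir Directory for TSV outputs and `report.json`; `NULL`
#'   keeps everything in memory.
#' @return List of class `"RunReport"`: `config`, `seed`, `counts`,
#'   `thresholds`, `warnings`, `timings`, plus `tables` (the named list
#'   of result tables) and `truth`.
#' @export
runPipeline <- function(config = list(), outDir = NULL) {
  if (is.character(config)) config <- readConfig(config)
  cfg <- utils::modifyList(.default_config(), config)
  warnings <- character()
  wh <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  timings <- c()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(wh(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timings[[name]] <<- as.numeric(Sys.time() - t0, units = "secs")
    res
  }

  params <- do.call(simParams, utils::modifyList(cfg$sim,
                                                 list(seed = cfg$seed)))
  truth <- stage("truth", buildTruth(params))
  geno <- stage("genotypes", simulateGenotypes(params))
  expr <- stage("expression", simulateExpression(geno, truth, params))
  trait <- stage("trait", simulateTrait(expr, geno, truth, params))
  if (cfg$nPcs > 0)
    expr <- stage("pc_correction",
                  residualizePCs(expr, geno, nPcs = cfg$nPcs,
                                 assocPThreshold = cfg$pcAssocThreshold))
  pairs <- stage("cis_pairs", selectCisPairs(geno, expr, cfg$window))
  eqtlF <- stage("map_F", mapEqtls(geno, expr, pairs, "F"))
  eqtlM <- stage("map_M", mapEqtls(geno, expr, pairs, "M"))
  eqtlC <- stage("meta", metaAnalyze(eqtlF, eqtlM))
  diff <- stage("diff_test", diffTestTables(eqtlF, eqtlM, cfg$fdrLevel))
  sel <- diff[diff$selected, , drop = FALSE]
  egenes <- unique(sel$unit_id)
  lead <- if (nrow(sel)) stage("lead", pickLeadEqtl(sel)) else sel
  gwas <- stage("gwas", computeSummaryStats(geno, trait))
  gwasF <- gwas[gwas$stratum == "F", , drop = FALSE]
  gwasM <- gwas[gwas$stratum == "M", , drop = FALSE]
  attr(gwasF, "standardized") <- attr(gwasM, "standardized") <- FALSE
  screen <- stage("gwas_screen",
                  gwasContrastScreen(lead, gwasF, gwasM, mEff = cfg$mEff,
                                     nEgenes = max(length(egenes), 1L)))
  fits <- stage("twmr", {
    lapply(c(F = "F", M = "M"), function(s) {
      et <- if (s == "F") eqtlF else eqtlM
      gt <- if (s == "F") gwasF else gwasM
      fl <- lapply(unique(et$unit_id), function(g) {
        inst <- buildInstrumentSet(et, gt, g, pInst = cfg$pInst,
                                   r2Prune = cfg$r2Prune)
        if (is.null(inst)) return(NULL)
        twmrFit(inst, stratum = s)
      })
      do.call(rbind, fl)
    })
  })
  contrast <- if (!is.null(fits$F) && !is.null(fits$M) &&
                  length(intersect(fits$F$gene_id[fits$F$focal],
                                   fits$M$gene_id[fits$M$focal])))
    stage("twmr_contrast", twmrSexContrast(fits$F, fits$M))
  else NULL
  power <- if (nrow(lead)) stage("power", {
    iF <- match(paste(lead$snp_id, lead$unit_id),
                paste(eqtlF$snp_id, eqtlF$unit_id))
    iM <- match(paste(lead$snp_id, lead$unit_id),
                paste(eqtlM$snp_id, eqtlM$unit_id))
    alpha_hat <- vapply(lead$unit_id, function(g) {
      a <- c(if (!is.null(fits$F)) fits$F$alpha[fits$F$gene_id == g & fits$F$focal],
             if (!is.null(fits$M)) fits$M$alpha[fits$M$gene_id == g & fits$M$focal])
      if (length(a)) mean(a) else NA_real_
    }, numeric(1L))
    pw <- powerSexDiff(alpha_hat, eqtlF$beta[iF], eqtlM$beta[iM],
                       cfg$powerNGwasF, cfg$powerNGwasM, crit = cfg$crit)
    data.frame(gene_id = lead$unit_id, snp_id = lead$snp_id,
               alpha_hat = alpha_hat, beta_F = eqtlF$beta[iF],
               beta_M = eqtlM$beta[iM], pw, row.names = NULL)
  }) else NULL

  report <- list(
    config = cfg,
    seed = cfg$seed,
    counts = list(
      pairs_tested = nrow(diff),
      pairs_significant = nrow(sel),
      egenes = length(egenes),
      lead_eqtls = nrow(lead),
      twmr_genes_F = if (is.null(fits$F)) 0L else sum(fits$F$focal),
      twmr_genes_M = if (is.null(fits$M)) 0L else sum(fits$M$focal),
      contrast_significant = if (is.null(contrast)) 0L
                             else sum(contrast$significant)),
    thresholds = list(
      fdr_level = cfg$fdrLevel,
      fdr_p_threshold = attr(diff, "pThreshold"),
      gwas_screen_threshold = attr(screen, "threshold"),
      m_eff = cfg$mEff,
      twmr_bonferroni = if (is.null(contrast)) NA_real_
                        else attr(contrast, "bonferroniThreshold")),
    warnings = warnings,
    timings = timings)
  tables <- list(eqtl_F = eqtlF, eqtl_M = eqtlM, eqtl_combined = eqtlC,
                 eqtl_diff = diff, lead_eqtls = lead, gwas = gwas,
                 gwas_contrast = screen, twmr_F = fits$F, twmr_M = fits$M,
                 twmr_contrast = contrast, power = power)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      tb <- tables[[nm]]
      if (is.null(tb)) next
      if (nm %in% c("eqtl_F", "eqtl_M", "eqtl_combined"))
        writeSummaryStats(tb, file.path(outDir, paste0(nm, ".tsv")))
      else writeTable(tb, file.path(outDir, paste0(nm, ".tsv")))
    }
    jsonlite::write_json(report[setdiff(names(report), "timings")],
                         file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  out <- c(report, list(tables = tables, truth = truth))
  class(out) <- "RunReport"
  out
}

#' @export
print.RunReport <- function(x, ...) {
  cat("Sex-dimorphism pipeline run (seed", x$seed, ")\n")
  cnt <- x$counts
  cat(sprintf("  pairs tested: %d; significant at FDR %.2g: %d (p <= %s)\n",
              cnt$pairs_tested, x$thresholds$fdr_level,
              cnt$pairs_significant,
              format(x$thresholds$fdr_p_threshold, digits = 3)))
  cat(sprintf("  sex-biased eGenes: %d (lead eQTLs: %d)\n",
              cnt$egenes, cnt$lead_eqtls))
  cat(sprintf("  TWMR genes F/M: %d/%d; contrast-significant: %d\n",
              cnt$twmr_genes_F, cnt$twmr_genes_M, cnt$contrast_significant))
  if (length(x$warnings))
    cat(sprintf("  warnings collected: %d\n", length(x$warnings)))
  invisible(x)
}
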