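#' @importFrom utils read.delim write.table
NULL

.SUMSTAT_COLS <- c("snp_id", "unit_id", "stratum", "beta", "se", "n", "p")

.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.10g", v)
  }, character(1L))
  out
}

#' Read a genotype dosage table
#'
#' Reads genotypes from either a tab-separated dosage table or a VCF file
#' into a [GenotypeExperiment-class]. The TSV dialect has one SNP per row
#' with header `snp_id chrom pos <ind1> <ind2> ...`; dosages must lie in
#' `[0, 2]` (`NA` marks missing). For VCF input, `DS` (dosage) FORMAT
#' fields are used when present, otherwise dosage is the count of
#' alternate alleles in the `GT` field; missing genotypes (`./.`) become
#' `NA`. Coordinates are 1-based throughout.
#'
#' @param path Path to the input file.
#' @param format `"tsv"` or `"vcf"`.
#' @return A [GenotypeExperiment-class].
#' @export
readGenotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") return(.read_genotypes_vcf(path))
  tab <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 4L || !identical(colnames(tab)[1:3], c("snp_id", "chrom", "pos")))
    stop("malformed genotype TSV header: expected 'snp_id\tchrom\tpos\t<individuals...>'")
  dos <- as.matrix(tab[, -(1:3), drop = FALSE])
  storage.mode(dos) <- "double"
  bad <- which(!is.na(dos) & (dos < 0 | dos > 2), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("dosage outside [0, 2] for SNP '%s' (row %d)",
                 tab$snp_id[bad[1L, 1L]], bad[1L, 1L]))
  GenotypeExperiment(t(dos), snpId = tab$snp_id, chrom = tab$chrom,
                     pos = as.integer(tab$pos))
}

.read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  miss <- is.na(ids) | ids == "."
  ids[miss] <- paste0(fix[miss, "CHROM"], ":", fix[miss, "POS"])
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      al <- strsplit(g, "[/|]")[[1L]]
      if (any(al == ".")) return(NA_real_)
      sum(as.integer(al) > 0L)
    })
  }
  GenotypeExperiment(t(ds), snpId = ids, chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]))
}

#' Read a summary-statistic table
#'
#' Reads a tab-separated table of per-stratum association effects with
#' header `snp_id unit_id stratum beta se n p`. `unit_id` is the gene (for
#' eQTL effects) or trait (for GWAS effects); `stratum` must be one of
#' `F`, `M`, `combined`. `se` may be `NA` for standardized effects whose
#' sampling variance is `1/n` (the convention used for rank-correlation
#' eQTL effects); GWAS tables carry an explicit `se`. An optional comment
#' header line `# standardized: TRUE/FALSE` declares which convention the
#' table uses; when absent it is inferred from whether every `se` is `NA`.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with the columns above, rows in file order, and
#'   attribute `"standardized"` (logical).
#' @export
readSummaryStats <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  std_flag <- NULL
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("standardized:\\s*(TRUE|FALSE)", first))[[1L]]
    if (length(m) == 2L) std_flag <- as.logical(m[2L])
  }
  tab <- read.delim(path, comment.char = "#", colClasses = c(
    snp_id = "character", unit_id = "character", stratum = "character",
    beta = "numeric", se = "numeric", n = "integer", p = "numeric"))
  if (!identical(colnames(tab), .SUMSTAT_COLS))
    stop("malformed summary-statistic header: expected ",
         paste(.SUMSTAT_COLS, collapse = "\t"))
  if (nrow(tab)) {
    bad <- which(!tab$stratum %in% .STRATA)
    if (length(bad))
      stop(sprintf("unknown stratum token '%s' in row %d (must be F, M or combined)",
                   tab$stratum[bad[1L]], bad[1L]))
    if (any(!is.na(tab$se) & tab$se < 0))
      stop("negative standard error in row ",
           which(!is.na(tab$se) & tab$se < 0)[1L])
    if (any(!is.na(tab$n) & tab$n <= 0L))
      stop("non-positive n in row ", which(!is.na(tab$n) & tab$n <= 0L)[1L])
    if (any(!is.na(tab$p) & (tab$p <= 0 | tab$p > 1)))
      stop("p outside (0, 1] in row ",
           which(!is.na(tab$p) & (tab$p <= 0 | tab$p > 1))[1L])
  }
  if (is.null(std_flag)) std_flag <- all(is.na(tab$se))
  attr(tab, "standardized") <- std_flag
  tab
}

#' Write a summary-statistic table
#'
#' Serializes a summary-statistic `data.frame` (columns as in
#' [readSummaryStats()]) with a fixed column order and numeric formatting
#' at 10 significant digits, so that a write/read cycle reproduces the
#' table exactly at that precision.
#'
#' @param records The table to write (may have zero rows).
#' @param path Output path.
#' @param standardized Logical header flag declaring the `var = 1/n`
#'   standardized-beta convention; defaults to the table's
#'   `"standardized"` attribute, or to whether all `se` are `NA`.
#' @return `path`, invisibly.
#' @export
writeSummaryStats <- function(records, path, standardized = NULL) {
  if (is.null(records)) stop("records must not be NULL")
  if (is.null(standardized))
    standardized <- attr(records, "standardized") %||% all(is.na(records$se))
  missing_cols <- setdiff(.SUMSTAT_COLS, colnames(records))
  if (length(missing_cols))
    stop("records lack required columns: ", paste(missing_cols, collapse = ", "))
  out <- records[, .SUMSTAT_COLS, drop = FALSE]
  for (cn in c("beta", "se", "p")) out[[cn]] <- .fmt_num(as.numeric(out[[cn]]))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# standardized: %s", standardized), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write any result table deterministically
#'
#' General-purpose TSV writer used for difference-test, TWMR and power
#' tables: fixed column order (as given), numeric columns rendered with 10
#' significant digits, no quoting.
#'
#' @param records A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTable <- function(records, path) {
  if (is.null(records)) stop("records must not be NULL")
  out <- records
  for (cn in colnames(out))
    if (is.numeric(out[[cn]]) && !is.integer(out[[cn]]))
      out[[cn]] <- .fmt_num(out[[cn]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an analysis configuration file
#'
#' Reads a YAML key-value configuration (paths, simulation scenario,
#' window size, thresholds, seed) into a named list as consumed by
#' [runPipeline()].
#'
#' @param path Path to a YAML file.
#' @return Named list.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  yaml::read_yaml(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
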