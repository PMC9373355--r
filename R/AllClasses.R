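#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData rowData<- rowRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

.SEX_LEVELS <- c("F", "M")
.STRATA <- c("F", "M", "combined")

#' Container for genotype dosages with SNP positions
#'
#' `GenotypeExperiment` extends
#' [`RangedSummarizedExperiment`][SummarizedExperiment::RangedSummarizedExperiment-class]
#' with a single `"dosage"` assay holding allele dosages in `[0, 2]`
#' (SNPs in rows, individuals in columns). SNP coordinates are 1-based and
#' stored as the `rowRanges`; the per-SNP minor allele frequency lives in
#' `rowData(x)$maf`. When sex labels are known they are stored in
#' `colData(x)$sex` as literal `"F"`/`"M"` strings.
#'
#' Missing genotypes are encoded as `NA`; all downstream statistics drop
#' incomplete observations pairwise.
#'
#' @aliases GenotypeExperiment-class
#' @seealso [GenotypeExperiment()] the constructor, [dosageMatrix()],
#'   [snpInfo()], [sexLabels()].
#' @exportClass GenotypeExperiment
setClass("GenotypeExperiment", contains = "RangedSummarizedExperiment")

#' Container for expression values with gene center positions
#'
#' `ExpressionExperiment` extends
#' [`RangedSummarizedExperiment`][SummarizedExperiment::RangedSummarizedExperiment-class]
#' with a single `"expr"` assay (genes in rows, individuals in columns).
#' Each gene carries a 1-based center position in its `rowRanges`, the
#' coordinate against which the cis window is measured.
#'
#' @aliases ExpressionExperiment-class
#' @seealso [ExpressionExperiment()] the constructor, [exprMatrix()],
#'   [geneInfo()], [sexLabels()].
#' @exportClass ExpressionExperiment
setClass("ExpressionExperiment", contains = "RangedSummarizedExperiment")

.validate_sex <- function(sex) {
  if (is.null(sex)) return(NULL)
  if (!all(sex %in% .SEX_LEVELS))
    return(sprintf(
      "sex labels must be the literal strings %s (got: %s)",
      paste(dQuote(.SEX_LEVELS, '"'), collapse = "/"),
      paste(unique(setdiff(sex, .SEX_LEVELS)), collapse = ", ")))
  NULL
}

setValidity("GenotypeExperiment", function(object) {
  msg <- character()
  if (!"dosage" %in% names(assays(object)))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    bad <- which(!is.na(d) & (d < 0 | d > 2))
    if (length(bad))
      msg <- c(msg, sprintf("dosages must lie in [0, 2] or be NA (%d offending values, first at index %d)",
                            length(bad), bad[1L]))
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "SNP identifiers must be unique")
  if ("maf" %in% colnames(rowData(object))) {
    maf <- rowData(object)$maf
    if (any(!is.na(maf) & (maf <= 0 | maf > 0.5)))
      msg <- c(msg, "maf must lie in (0, 0.5]")
  }
  if ("sex" %in% colnames(colData(object))) {
    m <- .validate_sex(colData(object)$sex)
    if (!is.null(m)) msg <- c(msg, m)
  }
  if (length(msg)) msg else TRUE
})

setValidity("ExpressionExperiment", function(object) {
  msg <- character()
  if (!"expr" %in% names(assays(object)))
    msg <- c(msg, "assay 'expr' is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene identifiers must be unique")
  if ("sex" %in% colnames(colData(object))) {
    m <- .validate_sex(colData(object)$sex)
    if (!is.null(m)) msg <- c(msg, m)
  }
  if (length(msg)) msg else TRUE
})

.feature_granges <- function(chrom, pos, ids) {
  if (any(pos < 1)) stop("positions must be strictly positive (1-based)")
  gr <- GRanges(as.character(chrom), IRanges(start = as.integer(pos), width = 1L))
  names(gr) <- ids
  gr
}

#' Construct a GenotypeExperiment
#'
#' @param dosages Numeric matrix of allele dosages, individuals in rows and
#'   SNPs in columns (the natural regression orientation); transposed
#'   internally to the feature-by-sample layout. Values must be in `[0, 2]`
#'   or `NA`.
#' @param snpId Character vector of unique SNP identifiers.
#' @param chrom Chromosome name per SNP.
#' @param pos 1-based SNP position.
#' @param maf Optional minor allele frequency per SNP in `(0, 0.5]`; when
#'   omitted it is estimated from the dosages (folded allele frequency).
#' @param sex Optional per-individual sex labels, literal `"F"`/`"M"`.
#' @return A [GenotypeExperiment-class] object.
#' @examples
#' g <- GenotypeExperiment(matrix(c(0, 1, 2), 3, 1), "rs1", "1", 500L)
#' dosageMatrix(g)
#' @export
GenotypeExperiment <- function(dosages, snpId, chrom, pos, maf = NULL,
                               sex = NULL) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != length(snpId))
    stop("ncol(dosages) must equal length(snpId)")
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("ind%05d", seq_len(nrow(dosages)))
  m <- t(dosages)
  dimnames(m) <- list(snpId, rownames(dosages))
  if (is.null(maf)) {
    p <- rowMeans(m, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    maf[maf == 0] <- NA_real_  # monomorphic: no defined MAF
  }
  rr <- .feature_granges(chrom, pos, snpId)
  cd <- DataFrame(row.names = colnames(m))
  if (!is.null(sex)) {
    if (length(sex) != ncol(m))
      stop("length(sex) must equal the number of individuals")
    cd$sex <- as.character(sex)
  }
  se <- SummarizedExperiment(assays = list(dosage = m), rowRanges = rr,
                             colData = cd)
  rowData(se)$maf <- as.numeric(maf)
  new("GenotypeExperiment", se)
}

#' Construct an ExpressionExperiment
#'
#' @param values Numeric matrix of expression values, individuals in rows
#'   and genes in columns; transposed internally.
#' @param geneId Character vector of unique gene identifiers.
#' @param chrom Chromosome name per gene.
#' @param centerPos 1-based center position of the gene (or probe), the
#'   coordinate used by the cis-window rule.
#' @param sex Optional per-individual sex labels, literal `"F"`/`"M"`.
#' @return An [ExpressionExperiment-class] object.
#' @examples
#' e <- ExpressionExperiment(matrix(rnorm(6), 3, 2), c("g1", "g2"),
#'                           c("1", "1"), c(1e6, 4e6))
#' geneInfo(e)
#' @export
ExpressionExperiment <- function(values, geneId, chrom, centerPos,
                                 sex = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != length(geneId))
    stop("ncol(values) must equal length(geneId)")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("ind%05d", seq_len(nrow(values)))
  m <- t(values)
  dimnames(m) <- list(geneId, rownames(values))
  rr <- .feature_granges(chrom, centerPos, geneId)
  cd <- DataFrame(row.names = colnames(m))
  if (!is.null(sex)) {
    if (length(sex) != ncol(m))
      stop("length(sex) must equal the number of individuals")
    cd$sex <- as.character(sex)
  }
  se <- SummarizedExperiment(assays = list(expr = m), rowRanges = rr,
                             colData = cd)
  new("ExpressionExperiment", se)
}

#' Accessors for genotype and expression containers
#'
#' `dosageMatrix()` and `exprMatrix()` return the individuals-by-features
#' matrices (transposing the internal feature-by-sample storage);
#' `snpInfo()`/`geneInfo()` return a `data.frame` of feature annotation with
#' 1-based positions; `sexLabels()` returns the per-individual `"F"`/`"M"`
#' labels stored in `colData`, or errors when absent and `required = TRUE`.
#'
#' @param x A [GenotypeExperiment-class] or [ExpressionExperiment-class].
#' @param required For `sexLabels()`: error when labels are absent?
#' @return See each accessor's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' @rdname accessors
#' @export
setMethod("dosageMatrix", "GenotypeExperiment", function(x)
  t(assay(x, "dosage")))

#' @rdname accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @rdname accessors
#' @export
setMethod("exprMatrix", "ExpressionExperiment", function(x)
  t(assay(x, "expr")))

#' @rdname accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname accessors
#' @export
setMethod("snpInfo", "GenotypeExperiment", function(x)
  data.frame(snp_id = rownames(x),
             chrom = as.character(seqnames(rowRanges(x))),
             pos = start(rowRanges(x)),
             maf = rowData(x)$maf,
             row.names = NULL))

#' @rdname accessors
#' @export
setGeneric("geneInfo", function(x) standardGeneric("geneInfo"))

#' @rdname accessors
#' @export
setMethod("geneInfo", "ExpressionExperiment", function(x)
  data.frame(gene_id = rownames(x),
             chrom = as.character(seqnames(rowRanges(x))),
             center_pos = start(rowRanges(x)),
             row.names = NULL))

#' @rdname accessors
#' @export
setGeneric("sexLabels", function(x, required = TRUE)
  standardGeneric("sexLabels"))

.sex_from_coldata <- function(x, required) {
  if (!"sex" %in% colnames(colData(x))) {
    if (required)
      stop("no sex labels stored in colData(x)$sex")
    return(NULL)
  }
  sex <- colData(x)$sex
  if (required && length(unique(sex)) < 2L)
    stop("both sex strata must be non-empty for stratified operations")
  sex
}

#' @rdname accessors
#' @export
setMethod("sexLabels", "GenotypeExperiment", .sex_from_coldata)

#' @rdname accessors
#' @export
setMethod("sexLabels", "ExpressionExperiment", .sex_from_coldata)

setMethod("show", "GenotypeExperiment", function(object) {
  cat(sprintf("GenotypeExperiment: %d SNPs x %d individuals\n",
              nrow(object), ncol(object)))
  sex <- .sex_from_coldata(object, required = FALSE)
  if (!is.null(sex))
    cat(sprintf("  sex: %d F / %d M\n", sum(sex == "F"), sum(sex == "M")))
  maf <- rowData(object)$maf
  if (length(maf) && !all(is.na(maf)))
    cat(sprintf("  MAF range: [%.3f, %.3f]\n",
                min(maf, na.rm = TRUE), max(maf, na.rm = TRUE)))
  invisible(NULL)
})

setMethod("show", "ExpressionExperiment", function(object) {
  cat(sprintf("ExpressionExperiment: %d genes x %d individuals\n",
              nrow(object), ncol(object)))
  sex <- .sex_from_coldata(object, required = FALSE)
  if (!is.null(sex))
    cat(sprintf("  sex: %d F / %d M\n", sum(sex == "F"), sum(sex == "M")))
  invisible(NULL)
})
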