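#' GenotypeExperiment: categorical genotypes with a case/control phenotype
#'
#' The central data container of the package. It extends
#' [SummarizedExperiment::SummarizedExperiment] with SNPs as rows and subjects
#' as columns. The single assay `"genotype"` holds integer genotype codes:
#'
#' * `encoding = "initial"` — codes in `{0, 1, 2, 3}` for
#'   \{missing, homozygous minor (aa), heterozygous (aB/Ba),
#'   homozygous major (BB)\};
#' * `encoding = "binary"` — codes in `{0, 1}` (1 = the reference-cluster
#'   mode genotype, 0 = any other observed genotype) with `NA` for missing.
#'
#' The phenotype is stored in `colData(x)$phenotype` as a factor with levels
#' `c("control", "case")`.
#'
#' @slot encoding Either `"initial"` or `"binary"`.
#'
#' @seealso [genotypes()], [phenotype()], [binarizeMatrix()]
#' @export
setClass("GenotypeExperiment",
  contains = "SummarizedExperiment",
  representation(encoding = "character"),
  prototype(encoding = "initial")
)

setValidity("GenotypeExperiment", function(object) {
  msg <- character()
  if (!(length(object@encoding) == 1L &&
        object@encoding %in% c("initial", "binary")))
    msg <- c(msg, "encoding must be 'initial' or 'binary'")
  if (!"genotype" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'genotype' is required")
  else {
    g <- SummarizedExperiment::assay(object, "genotype")
    if (identical(object@encoding, "initial")) {
      if (anyNA(g) || !all(g %in% 0:3))
        msg <- c(msg, "initial-encoding genotypes must be in {0,1,2,3}")
    } else {
      if (!all(g[!is.na(g)] %in% 0:1))
        msg <- c(msg, "binary-encoding genotypes must be in {0,1} or NA")
    }
  }
  if (!"phenotype" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'phenotype' column")
  else {
    ph <- SummarizedExperiment::colData(object)$phenotype
    if (!is.factor(ph) || !identical(levels(ph), c("control", "case")))
      msg <- c(msg, "phenotype must be a factor with levels control, case")
    if (anyNA(ph))
      msg <- c(msg, "phenotype must not contain NA")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "SNP ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "subject ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeExperiment
#'
#' @param genotypes Integer matrix of genotype codes, subjects in rows and
#'   SNPs in columns (the conventional layout of a genotype table; it is
#'   transposed into the SNPs-by-subjects assay internally). Codes must be in
#'   `{0,1,2,3}` (0 = missing).
#' @param phenotype Vector of case/control labels, one per subject. Accepted
#'   codings: `0/1` (0 = control), `"control"/"case"`, or PLINK-style `1/2`
#'   (1 = control); see `phenotypeCoding`.
#' @param snpIds,subjectIds Optional ids; defaults taken from `dimnames` or
#'   synthesized (`SNP_1..`, `S1..`).
#' @param geneLabels Optional character vector of gene labels parallel to the
#'   SNPs.
#' @param phenotypeCoding One of `"01"`, `"labels"`, `"12"` or `"auto"`.
#' @param encoding `"initial"` (default) or `"binary"`.
#' @return A [GenotypeExperiment-class] object.
#' @export
#' @examples
#' g <- matrix(c(1, 2, 3, 3, 2, 1), nrow = 3,
#'             dimnames = list(NULL, c("rs1", "rs2")))
#' ge <- GenotypeExperiment(g, phenotype = c(1, 0, 1))
#' ge
GenotypeExperiment <- function(genotypes, phenotype,
                               snpIds = NULL, subjectIds = NULL,
                               geneLabels = NULL,
                               phenotypeCoding = c("auto", "01", "labels", "12"),
                               encoding = c("initial", "binary")) {
  encoding <- match.arg(encoding)
  genotypes <- as.matrix(genotypes)
  if (is.null(snpIds))
    snpIds <- colnames(genotypes) %||% paste0("SNP_", seq_len(ncol(genotypes)))
  if (is.null(subjectIds))
    subjectIds <- rownames(genotypes) %||% paste0("S", seq_len(nrow(genotypes)))
  ph <- .mapPhenotype(phenotype, match.arg(phenotypeCoding))
  if (length(ph) != nrow(genotypes))
    stop("phenotype length (", length(ph), ") does not match the number of ",
         "subjects (", nrow(genotypes), ")")
  storage.mode(genotypes) <- "integer"
  assay <- t(genotypes)
  dimnames(assay) <- list(snpIds, subjectIds)
  rd <- S4Vectors::DataFrame(snp_id = snpIds, row.names = snpIds)
  if (!is.null(geneLabels)) {
    stopifnot(length(geneLabels) == length(snpIds))
    rd$gene_label <- geneLabels
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(genotype = assay),
    rowData = rd,
    colData = S4Vectors::DataFrame(phenotype = ph, row.names = subjectIds)
  )
  new("GenotypeExperiment", se, encoding = encoding)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.mapPhenotype <- function(phenotype, coding) {
  raw <- phenotype
  if (is.factor(raw)) raw <- as.character(raw)
  if (coding == "auto") {
    coding <- if (is.character(raw)) "labels"
      else if (all(raw %in% c(0, 1, NA))) "01"
      else if (all(raw %in% c(1, 2, NA))) "12"
      else stop("cannot infer phenotype coding from values: ",
                paste(utils::head(unique(raw)), collapse = ", "))
  }
  lab <- switch(coding,
    "01" = {
      if (!all(raw %in% c(0, 1, NA)))
        stop("phenotype coding '01' expects values in {0,1}")
      c("control", "case")[raw + 1L]
    },
    "12" = {
      if (!all(raw %in% c(1, 2, NA)))
        stop("phenotype coding '12' expects values in {1,2}")
      c("control", "case")[raw]
    },
    "labels" = {
      low <- tolower(raw)
      if (!all(low %in% c("control", "case", NA)))
        stop("phenotype coding 'labels' expects 'case'/'control'")
      low
    }
  )
  factor(lab, levels = c("control", "case"))
}

#' @describeIn GenotypeExperiment-class Genotype codes as a subjects-by-SNPs
#'   integer matrix.
#' @param x A `GenotypeExperiment`.
#' @export
genotypes <- function(x) {
  stopifnot(is(x, "GenotypeExperiment"))
  t(SummarizedExperiment::assay(x, "genotype"))
}

#' @describeIn GenotypeExperiment-class Phenotype factor (levels
#'   `control`, `case`).
#' @export
phenotype <- function(x) {
  stopifnot(is(x, "SummarizedExperiment"))
  SummarizedExperiment::colData(x)$phenotype
}

#' @describeIn GenotypeExperiment-class SNP identifiers.
#' @export
snpIds <- function(x) rownames(x)

#' @describeIn GenotypeExperiment-class Subject identifiers.
#' @export
subjectIds <- function(x) colnames(x)

#' @describeIn GenotypeExperiment-class Gene labels parallel to [snpIds()],
#'   or `NULL` when not set.
#' @export
geneLabels <- function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if ("gene_label" %in% colnames(rd)) rd$gene_label else NULL
}

#' @describeIn GenotypeExperiment-class The genotype encoding, `"initial"`
#'   or `"binary"`.
#' @export
genotypeEncoding <- function(x) {
  stopifnot(is(x, "GenotypeExperiment"))
  x@encoding
}

.checkBothClasses <- function(ph) {
  n <- table(ph)
  if (any(n == 0))
    stop("both phenotype classes must be present (have ",
         paste(names(n), n, sep = "=", collapse = ", "), ")")
  invisible(n)
}

setMethod("show", "GenotypeExperiment", function(object) {
  ph <- phenotype(object)
  cat("GenotypeExperiment (", object@encoding, " encoding): ",
      ncol(object), " subjects x ", nrow(object), " SNPs\n", sep = "")
  cat("  cases: ", sum(ph == "case"), "  controls: ",
      sum(ph == "control"), "\n", sep = "")
  cat("  snpIds: ", paste(utils::head(rownames(object), 5), collapse = ", "),
      if (nrow(object) > 5) ", ..." else "", "\n", sep = "")
})
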