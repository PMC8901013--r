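#' Read a genotype table with a case/control phenotype
#'
#' Reads either a delimited text table in the package's categorical coding
#' (`{0,1,2,3}` = \{missing, aa, aB/Ba, BB\}) or a PLINK `.raw` additive
#' export, and returns a [GenotypeExperiment-class].
#'
#' For `format = "csv"`: one row per subject; an optional subject-id column
#' (`idColumn`), one phenotype column (`phenotypeColumn`), every remaining
#' column a SNP coded `{0,1,2,3}`.
#'
#' For `format = "plink_raw"`: whitespace-delimited with header
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one column per SNP holding
#' additive minor-allele counts. Counts are recoded
#' `2 -> 1 (aa)`, `1 -> 2 (het)`, `0 -> 3 (BB)`, `NA -> 0 (missing)`, and the
#' PLINK phenotype coding `1/2` = control/case is assumed. Trailing `_A`
#' allele suffixes are stripped from SNP names.
#'
#' Subjects whose phenotype is missing or unmappable are dropped with a
#' warning (a cohort must account for every subject, so ambiguous ones are
#' rejected rather than guessed). An error is raised if only one class
#' remains.
#'
#' @param path File path.
#' @param format `"csv"` or `"plink_raw"`.
#' @param phenotypeColumn Name of the phenotype column (CSV only; default
#'   `"phenotype"`).
#' @param idColumn Optional name of a subject-id column (CSV only). When
#'   absent, row indices are used.
#' @param phenotypeCoding Phenotype value coding, see [GenotypeExperiment()].
#' @param sep Field separator for `format = "csv"` (default `","`).
#' @return A [GenotypeExperiment-class].
#' @export
readGenotypeTable <- function(path, format = c("csv", "plink_raw"),
                              phenotypeColumn = "phenotype",
                              idColumn = NULL,
                              phenotypeCoding = "auto",
                              sep = ",") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "plink_raw") return(.readPlinkRaw(path))

  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!phenotypeColumn %in% names(df))
    stop("phenotype column '", phenotypeColumn, "' not found in ", path)
  subjectIds <- if (!is.null(idColumn)) {
    if (!idColumn %in% names(df))
      stop("id column '", idColumn, "' not found in ", path)
    as.character(df[[idColumn]])
  } else as.character(seq_len(nrow(df)))
  snpCols <- setdiff(names(df), c(phenotypeColumn, idColumn))
  if (!length(snpCols)) stop("no SNP columns found in ", path)

  geno <- as.matrix(df[snpCols])
  bad <- which(!(geno %in% 0:3) | is.na(geno), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("unknown genotype symbol '", geno[bad[1, , drop = FALSE]],
         "' at row ", bad[1, 1], ", column '", snpCols[bad[1, 2]],
         "' of ", path, " (expected codes 0,1,2,3)")
  }
  .assembleGE(geno, df[[phenotypeColumn]], snpCols, subjectIds,
              phenotypeCoding)
}

.readPlinkRaw <- function(path) {
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE, na.strings = c("NA", "-9"))
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(fixed %in% names(df)))
    stop("not a PLINK .raw file (missing ",
         paste(setdiff(fixed, names(df)), collapse = ", "), "): ", path)
  snpCols <- setdiff(names(df), fixed)
  if (!length(snpCols)) stop("no SNP columns found in ", path)
  counts <- as.matrix(df[snpCols])
  bad <- which(!(counts %in% c(0, 1, 2)) & !is.na(counts), arr.ind = TRUE)
  if (nrow(bad))
    stop("unknown genotype count '", counts[bad[1, , drop = FALSE]],
         "' at row ", bad[1, 1], ", column '", snpCols[bad[1, 2]],
         "' of ", path)
  geno <- plinkRecode(counts)
  snpIds <- sub("_[ACGT]$", "", snpCols)
  subjectIds <- make.unique(paste(df$FID, df$IID, sep = "_"))
  .assembleGE(geno, df$PHENOTYPE, snpIds, subjectIds, phenotypeCoding = "12")
}

#' Recode PLINK additive minor-allele counts to categorical genotype codes
#'
#' The map is `2 -> 1` (aa), `1 -> 2` (aB/Ba), `0 -> 3` (BB), `NA -> 0`
#' (missing): a bijection from `{0, 1, 2, NA}` onto `{3, 2, 1, 0}`.
#'
#' @param counts Numeric vector or matrix of additive counts.
#' @return Integer codes with the shape of `counts`.
#' @export
#' @examples
#' plinkRecode(c(0, 1, 2, NA))  # 3 2 1 0
plinkRecode <- function(counts) {
  out <- 3L - as.integer(counts)
  out[is.na(counts)] <- 0L
  if (is.matrix(counts)) dim(out) <- dim(counts)
  out
}

.assembleGE <- function(geno, phenoRaw, snpIds, subjectIds, phenotypeCoding) {
  drop <- is.na(phenoRaw) | (is.character(phenoRaw) & phenoRaw == "")
  if (any(drop)) {
    warning(sum(drop), " subject(s) with missing/ambiguous phenotype rejected")
    geno <- geno[!drop, , drop = FALSE]
    phenoRaw <- phenoRaw[!drop]
    subjectIds <- subjectIds[!drop]
  }
  ge <- GenotypeExperiment(geno, phenoRaw, snpIds = snpIds,
                           subjectIds = subjectIds,
                           phenotypeCoding = phenotypeCoding)
  .checkBothClasses(phenotype(ge))
  ge
}

#' Write a GenotypeExperiment as a CSV genotype table
#'
#' Inverse of [readGenotypeTable()] for `format = "csv"`: subject ids in
#' column `subject`, phenotype coded 0/1 in column `phenotype`, SNPs after.
#'
#' @param x A [GenotypeExperiment-class] (initial encoding).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeGenotypeTable <- function(x, path) {
  stopifnot(is(x, "GenotypeExperiment"), genotypeEncoding(x) == "initial")
  df <- data.frame(subject = subjectIds(x),
                   phenotype = as.integer(phenotype(x) == "case"),
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(genotypes(x), check.names = FALSE))
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a results table as TSV
#'
#' Shared serializer for all pipeline outputs. Numeric columns are formatted
#' at 6 significant digits; rows are ordered by the SNP-tuple columns
#' (`snp1`, `snp2`, `snp3` where present, lexicographically) so output is
#' deterministic, and ties are kept in input order.
#'
#' @param records A data.frame of result records (may have zero rows).
#' @param path Output path.
#' @param sortBySnps Order rows by SNP-tuple columns when present
#'   (default `TRUE`).
#' @return Invisibly, `path`.
#' @export
writeResultsTable <- function(records, path, sortBySnps = TRUE) {
  stopifnot(is.data.frame(records))
  df <- as.data.frame(records)
  tupleCols <- intersect(c("snp1", "snp2", "snp3", "snp_id", "cluster_id"),
                         names(df))
  if (sortBySnps && length(tupleCols) && nrow(df)) {
    keys <- lapply(df[tupleCols], function(v) if (is.numeric(v)) v
                   else as.character(v))
    df <- df[do.call(.lexOrder, keys), , drop = FALSE]
  }
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read back a TSV written by [writeResultsTable()]
#'
#' @param path File path.
#' @return A data.frame.
#' @export
readResultsTable <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}
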