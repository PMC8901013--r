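#' Per-SNP fraction of missing genotypes
#'
#' @param column Integer genotype codes in `{0,1,2,3}`; 0 is missing.
#' @return Proportion of missing codes in `[0, 1]`.
#' @export
#' @examples
#' missingFraction(c(0, 1, 2, 3, 0, 1, 2, 3, 1, 2))  # 0.2
missingFraction <- function(column) {
  if (!length(column)) stop("empty genotype column")
  stopifnot(all(column %in% 0:3))
  mean(column == 0L)
}

#' Minor allele frequency of a SNP column
#'
#' MAF = (2 n_aa + n_het) / (2 (n_aa + n_het + n_BB)), missing genotypes
#' excluded. If the raw frequency exceeds 0.5 the coding of the SNP is
#' inverted (the "minor" allele is actually the major one); the returned
#' value is then `1 - maf` and the `flipped` attribute is `TRUE`.
#'
#' @param column Integer genotype codes in `{0,1,2,3}`.
#' @return MAF in `[0, 0.5]`, with attribute `flipped`.
#' @export
#' @examples
#' minorAlleleFrequency(c(rep(1, 1), rep(2, 2), rep(3, 7)))  # 0.2
minorAlleleFrequency <- function(column) {
  stopifnot(all(column %in% 0:3))
  obs <- column[column != 0L]
  if (!length(obs)) stop("all genotypes missing; MAF undefined")
  n_aa <- sum(obs == 1L); n_het <- sum(obs == 2L)
  maf <- (2 * n_aa + n_het) / (2 * length(obs))
  flipped <- maf > 0.5
  if (flipped) maf <- 1 - maf
  structure(maf, flipped = flipped)
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' Pearson chi-square test of the observed genotype counts
#' `(n_aa, n_het, n_BB)` against the Hardy-Weinberg expectation
#' `(n q^2, 2 n p q, n p^2)`, with the allele frequency estimated from the
#' same counts; 1 degree of freedom.
#'
#' @param column Integer genotype codes in `{0,1,2,3}`.
#' @return A list with `statistic`, `p_value`, `df`, and `applicable`
#'   (`FALSE` for a monomorphic SNP, where the test is undefined and
#'   `statistic`/`p_value` are `NA`).
#' @export
#' @examples
#' hweTest(rep(c(1, 2, 2, 3), 25))$p_value  # counts (25,50,25): perfect HWE
hweTest <- function(column) {
  stopifnot(all(column %in% 0:3))
  obs <- column[column != 0L]
  if (!length(obs)) stop("all genotypes missing; HWE test undefined")
  counts <- c(aa = sum(obs == 1L), het = sum(obs == 2L), BB = sum(obs == 3L))
  n <- length(obs)
  q <- (2 * counts["aa"] + counts["het"]) / (2 * n)  # minor allele freq
  if (q == 0 || q == 1)
    return(list(statistic = NA_real_, p_value = NA_real_, df = 1L,
                applicable = FALSE))
  expected <- n * c(q^2, 2 * q * (1 - q), (1 - q)^2)
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = unname(stat),
       p_value = pchisq(unname(stat), df = 1, lower.tail = FALSE),
       df = 1L, applicable = TRUE)
}

#' Apply per-SNP quality control
#'
#' Step 1 of the framework. Filters are applied sequentially: SNPs with
#' *more than* `missingMax` missing genotypes are removed first; the MAF
#' filter (remove when MAF is *less than* `mafMin`; boundary values are
#' retained — both inequalities are strict) is then evaluated on the
#' survivors; an optional HWE filter runs last. MAF and HWE values are
#' reported for every SNP, but each filter's pass flag is only meaningful
#' for SNPs that survived the previous one, matching the sequential counts
#' a practitioner reports ("x failed missingness, then y more failed MAF").
#'
#' @param x A [GenotypeExperiment-class] (initial encoding).
#' @param missingMax Maximum tolerated missing fraction (default 0.05).
#' @param mafMin Minimum tolerated MAF (default 0.05).
#' @param hweAlpha Significance level for the HWE filter, or `NULL`
#'   (default) to disable it.
#' @param hweControlsOnly Test HWE in controls only (default `TRUE`,
#'   standard GWAS practice).
#' @return A list with `genotypes` (the filtered [GenotypeExperiment-class])
#'   and `report` (a data.frame with one row per input SNP: `snp_id`,
#'   `missing_fraction`, `maf`, `maf_flipped`, `hwe_p`, `pass_missing`,
#'   `pass_maf`, `pass_hwe`, `pass`, `fail_reason`), plus the thresholds
#'   used.
#' @export
applyQC <- function(x, missingMax = 0.05, mafMin = 0.05,
                    hweAlpha = NULL, hweControlsOnly = TRUE) {
  stopifnot(is(x, "GenotypeExperiment"), genotypeEncoding(x) == "initial",
            missingMax >= 0, missingMax <= 1, mafMin >= 0, mafMin <= 0.5)
  g <- genotypes(x)
  ph <- phenotype(x)
  nSnp <- ncol(g)

  missFrac <- colMeans(g == 0L)
  maf <- rep(NA_real_, nSnp)
  flip <- rep(NA, nSnp)
  for (j in seq_len(nSnp)) {
    if (any(g[, j] != 0L)) {
      m <- minorAlleleFrequency(g[, j])
      maf[j] <- as.numeric(m); flip[j] <- attr(m, "flipped")
    }
  }
  passMissing <- missFrac <= missingMax           # "more than" is strict
  passMaf <- !is.na(maf) & maf >= mafMin          # "less than" is strict

  hweP <- rep(NA_real_, nSnp)
  passHwe <- rep(TRUE, nSnp)
  if (!is.null(hweAlpha)) {
    sub <- if (hweControlsOnly) g[ph == "control", , drop = FALSE] else g
    for (j in seq_len(nSnp)) {
      if (any(sub[, j] != 0L)) {
        h <- hweTest(sub[, j])
        hweP[j] <- h$p_value
        if (h$applicable) passHwe[j] <- h$p_value >= hweAlpha
      }
    }
  }

  pass <- passMissing & passMaf & passHwe
  failReason <- rep("", nSnp)
  failReason[!passMissing] <- "missingness"
  failReason[passMissing & !passMaf] <- "maf"
  failReason[passMissing & passMaf & !passHwe] <- "hwe"

  report <- data.frame(
    snp_id = snpIds(x),
    missing_fraction = missFrac,
    maf = maf,
    maf_flipped = flip,
    hwe_p = hweP,
    pass_missing = passMissing,
    pass_maf = passMaf,
    pass_hwe = passHwe,
    pass = pass,
    fail_reason = failReason,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!any(pass)) {
    err <- simpleError("quality control removed every SNP")
    err$report <- report
    stop(err)
  }
  list(genotypes = x[pass, ], report = report,
       thresholds = list(missing_max = missingMax, maf_min = mafMin,
                         hwe_alpha = hweAlpha))
}
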