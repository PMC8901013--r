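test_that("missing fraction counts the zero code", {
  expect_equal(missingFraction(c(1, 2, 3, 2)), 0)
  expect_equal(missingFraction(c(0, 1, 2, 3, 0, 1, 2, 3, 1, 2)), 0.2)
  expect_equal(missingFraction(rep(0, 5)), 1)
  expect_error(missingFraction(integer(0)), "empty")
})

test_that("minor allele frequency counts alleles, excluding missing", {
  expect_equal(as.numeric(minorAlleleFrequency(c(2, 2, 2, 2))), 0.5)
  # n_aa = 1, n_het = 2, n_BB = 7: (2 + 2) / 20 = 0.2
  expect_equal(as.numeric(minorAlleleFrequency(c(1, 2, 2, rep(3, 7)))), 0.2)
  expect_equal(as.numeric(minorAlleleFrequency(rep(3, 6))), 0)
  # missing genotypes do not enter the denominator
  expect_equal(as.numeric(minorAlleleFrequency(c(0, 0, 2, 2))), 0.5)
  expect_error(minorAlleleFrequency(c(0, 0)), "missing")
})

test_that("inverted coding is folded back below 0.5 and flagged", {
  m <- minorAlleleFrequency(c(rep(1, 7), 2, 2, 3))  # raw freq 0.8
  expect_equal(as.numeric(m), 0.2)
  expect_true(attr(m, "flipped"))
  expect_false(attr(minorAlleleFrequency(c(1, 2, 3, 3)), "flipped"))
})

test_that("HWE test matches hand-computed goodness of fit", {
  perfect <- rep(c(1, 2, 2, 3), 25)           # counts (25, 50, 25)
  h <- hweTest(perfect)
  expect_equal(h$statistic, 0)
  expect_equal(h$p_value, 1)
  # counts (30, 40, 30): p_hat = 0.5, expected (25, 50, 25) -> 4.0
  h2 <- hweTest(rep(c(1, 2, 3), c(30, 40, 30)))
  expect_equal(h2$statistic, 4)
  expect_equal(h2$p_value, pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # all-heterozygous column: expected (25, 50, 25) -> 100
  h3 <- hweTest(rep(2, 100))
  expect_equal(h3$statistic, 100)
  # monomorphic SNP is flagged not-applicable
  h4 <- hweTest(rep(3, 50))
  expect_false(h4$applicable)
  expect_true(is.na(h4$statistic))
})

test_that("QC removes by missingness then MAF and reports each cause", {
  set.seed(42)
  n <- 100
  g <- matrix(sample(1:3, n * 10, replace = TRUE,
                     prob = c(0.09, 0.42, 0.49)), n, 10,
              dimnames = list(NULL, paste0("rs", 1:10)))
  g[1:10, 1] <- 0L                     # 10% missing
  g[1:10, 2] <- 0L                     # 10% missing
  g[, 3] <- c(2L, rep(3L, n - 1))      # MAF 0.005
  ge <- makeGE(g, rep_len(c(0, 1), n))
  qc <- applyQC(ge)
  expect_equal(nrow(qc$genotypes), 7L)
  expect_identical(qc$report$fail_reason[1:3],
                   c("missingness", "missingness", "maf"))
  expect_true(all(qc$report$pass[4:10]))
})

test_that("permissive thresholds keep every SNP", {
  set.seed(7)
  g <- matrix(sample(0:3, 200, replace = TRUE), 50, 4,
              dimnames = list(NULL, paste0("rs", 1:4)))
  ge <- makeGE(g, rep_len(c(0, 1), 50))
  qc <- applyQC(ge, missingMax = 1, mafMin = 0)
  expect_equal(nrow(qc$genotypes), 4L)
})

test_that("boundary SNPs are retained: removal inequalities are strict", {
  n <- 100
  # exactly 5% missing (with a healthy MAF) and MAF exactly 5%
  col1 <- c(rep(0L, 5), rep(2L, 20), rep(3L, 75))
  col2 <- c(rep(2L, 10), rep(3L, 90))  # MAF 10/200 = 0.05
  ok <- matrix(rep(c(1L, 2L, 3L), length.out = n))
  g <- cbind(rs_miss = col1, rs_maf = col2, rs_ok = ok[, 1])
  qc <- applyQC(makeGE(g, rep_len(c(0, 1), n)))
  expect_true(all(c("rs_miss", "rs_maf") %in% snpIds(qc$genotypes)))
})

test_that("QC is idempotent and MAF is subject-order invariant", {
  set.seed(11)
  g <- matrix(sample(0:3, 60 * 8, replace = TRUE,
                     prob = c(0.05, 0.1, 0.35, 0.5)), 60, 8,
              dimnames = list(NULL, paste0("rs", 1:8)))
  ge <- makeGE(g, rep_len(c(0, 1), 60))
  q1 <- applyQC(ge, missingMax = 0.1, mafMin = 0.1)
  q2 <- applyQC(q1$genotypes, missingMax = 0.1, mafMin = 0.1)
  expect_identical(genotypes(q1$genotypes), genotypes(q2$genotypes))
  for (j in 1:3) {
    col <- g[, j][g[, j] != 0 | TRUE]
    expect_equal(as.numeric(minorAlleleFrequency(col)),
                 as.numeric(minorAlleleFrequency(sample(col))))
  }
})

test_that("removing every SNP is an error carrying the report", {
  g <- cbind(rs1 = rep(0L, 20), rs2 = rep(0L, 20))
  g[1, ] <- 3L
  err <- tryCatch(applyQC(makeGE(g, rep_len(c(0, 1), 20))),
                  error = function(e) e)
  expect_match(conditionMessage(err), "every SNP")
  expect_s3_class(err$report, "data.frame")
})

test_that("optional HWE filter tests controls by default", {
  n <- 200
  set.seed(3)
  hweOk <- sample(1:3, n, TRUE, prob = c(0.25, 0.5, 0.25))
  hweBad <- rep(2L, n)   # all-het: gross HWE violation
  g <- cbind(rs_ok = hweOk, rs_bad = hweBad)
  ge <- makeGE(g, rep_len(c(0, 1), n))
  qc <- applyQC(ge, hweAlpha = 0.001)
  expect_false(qc$report$pass[qc$report$snp_id == "rs_bad"])
  expect_true(qc$report$pass[qc$report$snp_id == "rs_ok"])
  expect_identical(qc$report$fail_reason[qc$report$snp_id == "rs_bad"],
                   "hwe")
})
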