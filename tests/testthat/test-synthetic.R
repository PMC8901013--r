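test_that("simulated genotypes respect MAF and Hardy-Weinberg structure", {
  g <- simulateGenotypes(5000, c(rs1 = 0.3), seed = 2)
  counts <- tabulate(g[, 1], 3)
  maf <- (2 * counts[1] + counts[2]) / (2 * 5000)
  expect_lt(abs(maf - 0.3), 0.02)
  # near-zero MAF degenerates to all homozygous major
  g0 <- simulateGenotypes(100, c(rs1 = 1e-9), seed = 1)
  expect_true(all(g0 == 3L))
  expect_error(simulateGenotypes(10, c(rs1 = 0.7)), "0, 0.5")
  expect_identical(simulateGenotypes(50, c(a = 0.2, b = 0.4), seed = 9),
                   simulateGenotypes(50, c(a = 0.2, b = 0.4), seed = 9))
})

test_that("null genotypes pass the HWE test at the nominal rate", {
  mafs <- stats::setNames(runif(100, 0.1, 0.5), paste0("rs", 1:100))
  g <- simulateGenotypes(800, mafs, seed = 31)
  pvals <- apply(g, 2, function(col) hweTest(col)$p_value)
  expect_gte(mean(pvals >= 0.01, na.rm = TRUE), 0.95)
})

test_that("phenotype simulation honours the logistic model", {
  g <- simulateGenotypes(2000, c(A = 0.3, B = 0.3), seed = 3)
  nullModel <- list(intercept = 0, terms = list())
  y <- simulatePhenotype(g, nullModel, seed = 4)
  expect_lt(abs(mean(y) - 0.5), 0.03)
  rare <- simulatePhenotype(g, list(intercept = -10), seed = 5)
  expect_lt(mean(rare), 0.01)
  expect_error(
    simulatePhenotype(g, list(intercept = 0, terms = list(
      list(snps = "Z", beta = 1))), seed = 1), "unknown SNP")
})

test_that("pure-interaction generation leaves main effects null", {
  set.seed(60)
  reps <- 60
  mainRej <- interEffect <- logical(reps)
  for (i in 1:reps) {
    g <- simulateGenotypes(2000, c(A = 0.5, B = 0.5), seed = 6000 + i)
    em <- list(intercept = 0,
               terms = list(list(snps = c("A", "B"), beta = 1)))
    y <- simulatePhenotype(g, em, coding = "symmetric", seed = 7000 + i)
    ge <- makeGE(g, y)
    oa <- oracleChi2(g[, 1], y)
    mainRej[i] <- pchisq(oa$stat, oa$df, lower.tail = FALSE) < 0.05
    r <- chi2Interaction(ge, c("A", "B"))
    interEffect[i] <- pRaw(r) < 0.05
  }
  # symmetric product coding at MAF 0.5 keeps single-SNP margins null
  expect_lt(mean(mainRej), 0.15)
  expect_gt(mean(interEffect), 0.5)
})

test_that("missingness injection matches its rate and is seeded", {
  g <- matrix(1L, 100, 100)
  expect_identical(injectMissing(g, 0, seed = 1), g)
  gm <- injectMissing(g, 0.5, seed = 2)
  expect_gt(mean(gm == 0L), 0.47)
  expect_lt(mean(gm == 0L), 0.53)
  expect_identical(injectMissing(g, 0.3, seed = 3),
                   injectMissing(g, 0.3, seed = 3))
})

test_that("noiseless class-conditional profiles reproduce their modes", {
  spec <- twoProfileSpec(seed = 17, corruption = 0, nCases = 30,
                         nControls = 20)
  sim <- simulateClusteredPopulation(spec)
  g <- genotypes(sim$genotypes)
  ph <- phenotype(sim$genotypes)
  expect_true(all(g[ph == "case", ] == 1L))
  expect_true(all(g[ph == "control", ] == 3L))
  expect_equal(sum(ph == "case"), 30L)
  expect_equal(sum(ph == "control"), 20L)
})

test_that("the overall missing fraction tracks the configured rate", {
  spec <- twoProfileSpec(seed = 23, corruption = 0.1)
  spec$missing_rate <- 0.04
  sim <- simulateClusteredPopulation(spec)
  frac <- mean(genotypes(sim$genotypes) == 0L)
  expect_lt(abs(frac - 0.04), 0.01)
})

test_that("effect-model generation fixes the class margins exactly", {
  spec <- clusteredInteractionSpec(seed = 8, nCases = 120, nControls = 100)
  sim <- simulateClusteredPopulation(spec)
  ph <- phenotype(sim$genotypes)
  expect_equal(sum(ph == "case"), 120L)
  expect_equal(sum(ph == "control"), 100L)
  expect_equal(length(sim$membership), 220L)
  sim2 <- simulateClusteredPopulation(spec)
  expect_identical(genotypes(sim$genotypes), genotypes(sim2$genotypes))
})

test_that("spec validation catches inconsistent profiles", {
  expect_error(syntheticSpec(10, 10), "either mafs or profiles")
  expect_error(syntheticSpec(10, 10, profiles = list(
    list(modes = c(1, 2), weight_cases = 0.6, weight_controls = 1,
         corruption = 0.1))), "sum to 1")
  expect_error(syntheticSpec(10, 10, profiles = list(
    list(modes = c(1, 2), weight_cases = 1, weight_controls = 1,
         corruption = 0.6))), "0, 0.5")
})
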