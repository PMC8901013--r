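test_that("Hamming distance counts differing positions, missing included", {
  expect_equal(hammingDistance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(hammingDistance(c(1, 2, 3), c(3, 2, 1)), 2)
  expect_equal(hammingDistance(c(0, 1), c(1, 1)), 1)
  expect_error(hammingDistance(1:3, 1:2), "length mismatch")
})

test_that("identical subjects collapse to a single unit mode", {
  g <- matrix(rep(c(1L, 2L, 3L, 2L), each = 40), 40, 4,
              dimnames = list(NULL, paste0("rs", 1:4)))
  ge <- makeGE(g, rep_len(c(0, 1), 40))
  m <- trainSOM(ge, 1, 2, epochs = 20, seed = 1)
  a <- assignClusters(m, ge)
  expect_equal(length(unique(a)), 1L)
  expect_true(all(unitModes(m)[unique(a), ] == c(1, 2, 3, 2)))
})

test_that("two well-separated profiles are recovered exactly at zero noise", {
  spec <- twoProfileSpec(seed = 3, corruption = 0, nCases = 50,
                         nControls = 50)
  sim <- simulateClusteredPopulation(spec)
  for (s in 1:10) {
    m <- trainSOM(sim$genotypes, 2, 1, epochs = 30, seed = s)
    a <- assignClusters(m, sim$genotypes)
    expect_setequal(unique(unitModes(m)[unique(a), 1]), c(1L, 3L))
    acc <- max(mean((a == a[1]) == (sim$membership == sim$membership[1])),
               mean((a != a[1]) == (sim$membership == sim$membership[1])))
    expect_equal(acc, 1)
  }
})

test_that("training is deterministic and subject-order invariant", {
  spec <- twoProfileSpec(seed = 12, nCases = 60, nControls = 60)
  sim <- simulateClusteredPopulation(spec)
  m1 <- trainSOM(sim$genotypes, 2, 2, epochs = 40, seed = 9)
  m2 <- trainSOM(sim$genotypes, 2, 2, epochs = 40, seed = 9)
  expect_identical(unitModes(m1), unitModes(m2))
  expect_identical(m1@counts, m2@counts)
  perm <- sample(ncol(sim$genotypes))
  mp <- trainSOM(sim$genotypes[, perm], 2, 2, epochs = 40, seed = 9)
  expect_identical(unitModes(m1), unitModes(mp))
  a1 <- assignClusters(m1, sim$genotypes)
  ap <- assignClusters(mp, sim$genotypes[, perm])
  expect_identical(unname(a1[perm]), unname(ap))
})

test_that("assignment ties break to the smallest unit index", {
  spec <- twoProfileSpec(seed = 1, corruption = 0, nCases = 20,
                         nControls = 20, nSnps = 2)
  sim <- simulateClusteredPopulation(spec)
  m <- trainSOM(sim$genotypes, 2, 1, epochs = 10, seed = 2)
  # modes are (1,1) and (3,3) in some unit order; (1,3) is equidistant
  g <- rbind(c(1L, 3L), c(1L, 3L))
  ge1 <- makeGE(g, c(0, 1), snpIds = snpIds(sim$genotypes))
  a <- assignClusters(m, ge1)
  expect_true(all(a == 1L))
})

test_that("every subject lands in exactly one cluster", {
  spec <- twoProfileSpec(seed = 4, nCases = 40, nControls = 40)
  sim <- simulateClusteredPopulation(spec)
  m <- trainSOM(sim$genotypes, 2, 2, epochs = 30, seed = 5)
  a <- assignClusters(m, sim$genotypes)
  expect_equal(length(a), 80L)
  expect_true(all(a %in% seq_len(nUnits(m))))
  expect_equal(sum(table(a)), 80L)
})

test_that("pearsonChi2 agrees with an independent computation", {
  expect_equal(pearsonChi2(rbind(c(40, 10), c(10, 40)))$statistic, 36)
  expect_equal(pearsonChi2(rbind(c(40, 10), c(10, 40)))$df, 1L)
  expect_equal(pearsonChi2(rbind(c(30, 15), c(60, 30)))$statistic, 0)
  expect_true(pearsonChi2(rbind(c(0, 0), c(3, 4), c(0, 0)))$degenerate)
  set.seed(31)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 8), 3, 2)
    got <- pearsonChi2(tab)
    f <- rep(rep(1:3, 2), as.vector(tab))
    y <- rep(rep(1:2, each = 3), as.vector(tab))
    want <- oracleChi2(f, y)
    expect_equal(got$statistic, want$stat, tolerance = 1e-12)
    expect_equal(got$df, as.integer(want$df))
  }
})

test_that("cluster evaluation matches hand-computed chi-square", {
  a <- rep(c(1, 2), each = 50)
  ph <- factor(c(rep("case", 25), rep("control", 25),
                 rep("case", 25), rep("control", 25)),
               levels = c("control", "case"))
  ev <- evaluateClustering(a, ph)
  expect_equal(ev$statistic, 0)
  expect_equal(ev$p_value, 1)
  ph2 <- factor(c(rep("case", 40), rep("control", 10),
                  rep("case", 10), rep("control", 40)),
                levels = c("control", "case"))
  ev2 <- evaluateClustering(a, ph2)
  expect_equal(ev2$statistic, 36)
  expect_equal(ev2$df, 1L)
  # proportional three-cluster table has statistic 0
  a3 <- rep(1:3, c(20, 40, 60))
  ph3 <- factor(unlist(lapply(c(20, 40, 60), function(n)
    rep(c("case", "control"), n / 2))), levels = c("control", "case"))
  expect_equal(evaluateClustering(a3, ph3)$statistic, 0)
  # single occupied cluster is flagged not-applicable
  ev1 <- evaluateClustering(rep(1, 20), ph3[1:20])
  expect_false(ev1$applicable)
  expect_true(is.na(ev1$p_value))
})

test_that("map-size selection is deterministic and prefers separation", {
  spec <- twoProfileSpec(seed = 21, nCases = 60, nControls = 60)
  sim <- simulateClusteredPopulation(spec)
  sizes <- list(c(2, 1), c(2, 2))
  s1 <- selectMapSize(sim$genotypes, sizes, kFolds = 2, repeats = 2,
                      epochs = 30, seed = 17)
  s2 <- selectMapSize(sim$genotypes, sizes, kFolds = 2, repeats = 2,
                      epochs = 30, seed = 17)
  expect_identical(s1$table, s2$table)
  expect_equal(min(s1$table$median_test_p), s1$best_p)
  # cases/controls split across profiles: clustering should be strongly
  # predictive on held-out data
  expect_lt(s1$best_p, 1e-6)
  # single candidate is returned unconditionally
  s3 <- selectMapSize(sim$genotypes, list(c(2, 1)), kFolds = 2,
                      repeats = 2, epochs = 30, seed = 17)
  expect_equal(s3$best_size, c(2, 1))
})

test_that("cluster summaries recompute member modes, excluding missing", {
  g <- rbind(c(3L, 0L), c(3L, 0L), c(2L, 2L),
             c(1L, 1L), c(1L, 1L), c(1L, 3L))
  colnames(g) <- c("rs1", "rs2")
  ge <- makeGE(g, c(1, 1, 0, 0, 0, 1))
  a <- c(1, 1, 1, 2, 2, 2)
  cs <- summarizeClusters(a, ge)
  expect_identical(cs$cluster_id, c(1, 2))
  expect_identical(cs$n_cases, c(2L, 1L))
  expect_identical(cs$majority_label, c("cases", "controls"))
  expect_identical(cs$mode_rs1, c(3L, 1L))
  expect_identical(cs$mode_rs2, c(2L, 1L))   # missing excluded from mode
})

test_that("majority ties are flagged and labelled by the rarer class", {
  g <- cbind(rs1 = rep(1L, 6))
  ge <- makeGE(g, c(1, 0, 1, 0, 0, 0))   # 2 cases, 4 controls overall
  cs <- summarizeClusters(c(1, 1, 2, 2, 2, 2), ge)
  expect_true(cs$tie[1])
  expect_identical(cs$majority_label[1], "cases")
})

test_that("reference cluster policy picks the deviant minority cluster", {
  cs <- data.frame(
    cluster_id = 1:4,
    n_cases = c(120, 90, 100, 30),
    n_controls = c(60, 70, 60, 110),
    majority_label = c("cases", "cases", "cases", "controls"),
    tie = FALSE, mode_rs1 = c(1L, 1L, 2L, 3L))
  expect_equal(chooseReferenceCluster(cs), 4)
  expect_equal(chooseReferenceCluster(cs, override = 2), 2)
  expect_error(chooseReferenceCluster(cs, override = 9), "does not exist")
  # all clusters share a majority label -> explicit choice required
  cs2 <- cs; cs2$majority_label <- "cases"
  expect_error(chooseReferenceCluster(cs2), "choose one explicitly")
  # equal cluster-count split falls back to the rarer class; among the
  # equally deviant candidates the larger cluster wins
  cs3 <- data.frame(cluster_id = 1:4,
                    n_cases = c(30, 15, 10, 10),
                    n_controls = c(10, 5, 40, 40),
                    majority_label = c("cases", "cases", "controls",
                                       "controls"),
                    tie = FALSE, mode_rs1 = 1L)
  expect_equal(chooseReferenceCluster(cs3), 1)
  # equal sizes too: the smaller id wins
  cs4 <- cs3
  cs4$n_cases[1:2] <- 15; cs4$n_controls[1:2] <- 5
  expect_equal(chooseReferenceCluster(cs4), 1)
})

test_that("binary encoding maps the reference mode to 1 and keeps missing", {
  g <- cbind(rs281437 = c(3L, 2L, 1L, 0L), rs2 = c(2L, 2L, 3L, 2L))
  ge <- makeGE(g, c(1, 0, 1, 0))
  ref <- c(rs281437 = 3L, rs2 = 2L)
  bin <- binarizeMatrix(ge, ref)
  expect_identical(genotypeEncoding(bin), "binary")
  expect_identical(unname(genotypes(bin)[, 1]), c(1L, 0L, 0L, NA))
  expect_identical(unname(genotypes(bin)[, 2]), c(1L, 1L, 0L, 1L))
  # a subject equal to the reference mode vector is all ones
  expect_identical(unname(genotypes(bin)[1, ]), c(1L, 1L))
  expect_error(binarizeMatrix(ge, c(rs281437 = 3L)), "missing for SNP")
  expect_error(binarizeMatrix(ge, c(rs281437 = 0L, rs2 = 2L)),
               "code in \\{1,2,3\\}")
})

test_that("re-encoding the binary matrix with its own reference modes is identity", {
  spec <- twoProfileSpec(seed = 14, nCases = 60, nControls = 60)
  sim <- simulateClusteredPopulation(spec)
  x <- sim$genotypes
  m <- trainSOM(x, 2, 1, epochs = 30, seed = 2)
  a <- assignClusters(m, x)
  cs <- summarizeClusters(a, x)
  ref <- chooseReferenceCluster(cs)
  bin <- binarizeMatrix(x, referenceModes(cs, ref))
  g <- genotypes(bin)
  expect_true(all(g[!is.na(g)] %in% 0:1))
  # member modes of the reference cluster in the binary coding are 1,
  # so re-applying the encoding reproduces the matrix
  csb <- summarizeClusters(a, bin)
  refModesB <- referenceModes(csb, ref)
  expect_true(all(refModesB == 1L))
  bin2 <- binarizeMatrix(bin, refModesB)
  expect_identical(genotypes(bin2), genotypes(bin))
})
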