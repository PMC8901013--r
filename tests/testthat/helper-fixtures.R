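# Shared fixture builders; everything is generated in code.

# GenotypeExperiment from a subjects x SNPs matrix with a 0/1 phenotype
makeGE <- function(g, pheno, ..., encoding = "initial") {
  GenotypeExperiment(g, pheno, encoding = encoding, ...)
}

# fully observed factorial design: every genotype combination of `levels`
# codes repeated `reps` times, phenotype alternating
factorialGE <- function(levels, nSnps, reps = 4, encoding = "initial") {
  g <- as.matrix(expand.grid(rep(list(levels), nSnps)))
  g <- g[rep(seq_len(nrow(g)), reps), , drop = FALSE]
  colnames(g) <- paste0("S", seq_len(nSnps))
  storage.mode(g) <- "integer"
  makeGE(g, rep_len(c(0L, 1L), nrow(g)), encoding = encoding)
}

# two well-separated genotype profiles (codes all-1 vs all-3)
twoProfileSpec <- function(seed, corruption = 0.1, nCases = 389,
                           nControls = 336, nSnps = 7) {
  syntheticSpec(
    nCases = nCases, nControls = nControls,
    profiles = list(
      list(modes = rep(1L, nSnps), weight_cases = 1, weight_controls = 0,
           corruption = corruption),
      list(modes = rep(3L, nSnps), weight_cases = 0, weight_controls = 1,
           corruption = corruption)),
    seed = seed)
}

# independent textbook Pearson chi-square (separate code path from the
# package kernel): builds the table with table() and sums (O-E)^2/E
oracleChi2 <- function(f, y) {
  tab <- table(f, y)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(list(stat = 0, df = 0))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(stat = sum((tab - E)^2 / E),
       df = (nrow(tab) - 1) * (ncol(tab) - 1))
}

# independent interaction decomposition for 2 or 3 SNP columns (no
# missing values), mirroring the definitions rather than the kernel
oracleInteraction <- function(cols, y) {
  k <- ncol(cols)
  paste_f <- function(j) apply(cols[, j, drop = FALSE], 1, paste,
                               collapse = "/")
  if (k == 2) {
    a <- oracleChi2(cols[, 1], y); b <- oracleChi2(cols[, 2], y)
    ab <- oracleChi2(paste_f(1:2), y)
    list(stat = ab$stat - a$stat - b$stat, df = ab$df - a$df - b$df)
  } else {
    a <- oracleChi2(cols[, 1], y); b <- oracleChi2(cols[, 2], y)
    cc <- oracleChi2(cols[, 3], y)
    jab <- oracleChi2(paste_f(1:2), y); jbc <- oracleChi2(paste_f(2:3), y)
    jac <- oracleChi2(paste_f(c(1, 3)), y)
    jabc <- oracleChi2(paste_f(1:3), y)
    iab <- list(stat = jab$stat - a$stat - b$stat, df = jab$df - a$df - b$df)
    ibc <- list(stat = jbc$stat - b$stat - cc$stat,
                df = jbc$df - b$df - cc$df)
    iac <- list(stat = jac$stat - a$stat - cc$stat,
                df = jac$df - a$df - cc$df)
    list(stat = jabc$stat - iab$stat - ibc$stat - iac$stat - a$stat -
           b$stat - cc$stat,
         df = jabc$df - iab$df - ibc$df - iac$df - a$df - b$df - cc$df)
  }
}

# attach scan attributes lost by rbind
asScan <- function(df, method, encoding) {
  attr(df, "method") <- method
  attr(df, "encoding") <- encoding
  attr(df, "coding") <- "as_is"
  df
}
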