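#' @useDynLib EpiSOM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats pchisq pnorm rbinom runif median sd complete.cases
#' @importFrom utils read.table read.csv write.table combn
NULL

#' Derive a stage seed from a global seed
#'
#' Each pipeline stage draws its random numbers from a seed derived
#' deterministically from the single global seed and the stage name, so a run
#' is reproducible end-to-end while stages stay independent.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. `"som"`, `"permutations"`).
#' @return An integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' deriveSeed(1L, "som")
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

## Order-invariant deterministic hash of each genotype row; used for SOM
## initialization and training tie-breaks. Exact in double arithmetic
## (values stay < 2^36 < 2^53).
.rowHash <- function(x) {
  h <- rep(7, nrow(x))
  for (j in seq_len(ncol(x))) h <- (h * 31 + x[, j]) %% 2147483647
  h
}

## radix ordering gives locale-independent lexicographic id sorting
.lexOrder <- function(...) order(..., method = "radix")

.isCount <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x) && x >= 0
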