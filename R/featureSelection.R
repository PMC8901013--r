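#' Rank SNPs by Random-Forest Mean Decrease in Gini
#'
#' Step 2 of the framework. A classification Random Forest with bootstrap
#' resampling is grown on the genotypes (each SNP entered as a nominal
#' factor; the missing code 0 is kept as its own level, consistently with
#' the clustering step) and SNPs are ranked by Mean Decrease in Gini.
#' The out-of-bag misclassification error is reported alongside.
#'
#' SNP columns are put in canonical (lexicographic id) order before the
#' forest is grown, so the ranking does not depend on the column order of
#' the input. Ties in importance are broken by lexicographic SNP id.
#'
#' @param x A [GenotypeExperiment-class].
#' @param nTrees Number of trees (default 50).
#' @param seed Integer seed; the run is reproducible bit-for-bit.
#' @return A data.frame (one row per SNP, sorted by decreasing importance)
#'   with columns `snp_id`, `gini_importance`, `rank`; attributes `n_trees`,
#'   `seed`, `oob_error`.
#' @export
rfImportance <- function(x, nTrees = 50, seed = 1L) {
  stopifnot(is(x, "GenotypeExperiment"))
  if (!.isCount(nTrees) || nTrees < 1) stop("nTrees must be a count >= 1")
  g <- genotypes(x)
  if (ncol(g) < 2) stop("need at least 2 SNPs to rank")
  .checkBothClasses(phenotype(x))
  ord <- .lexOrder(colnames(g))
  g <- g[, ord, drop = FALSE]
  if (all(apply(g, 2, function(col) max(col) == min(col)))) {
    # nothing to split on: every importance is 0 and no forest is needed
    out <- data.frame(snp_id = colnames(g), gini_importance = 0,
                      rank = seq_len(ncol(g)), stringsAsFactors = FALSE)
    attr(out, "n_trees") <- as.integer(nTrees)
    attr(out, "seed") <- as.integer(seed)
    attr(out, "oob_error") <- NA_real_
    return(out)
  }
  pred <- as.data.frame(lapply(as.data.frame(g), function(col)
    factor(col, levels = sort(unique(col)))), check.names = FALSE)
  colnames(pred) <- colnames(g)
  y <- phenotype(x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = pred, y = y, ntree = as.integer(nTrees))
  imp <- rf$importance[, "MeanDecreaseGini"]
  ids <- rownames(rf$importance)
  o <- order(-imp, ids, method = "radix")
  out <- data.frame(snp_id = ids[o], gini_importance = unname(imp[o]),
                    rank = seq_along(o), stringsAsFactors = FALSE)
  attr(out, "n_trees") <- as.integer(nTrees)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "oob_error") <- unname(rf$err.rate[nTrees, "OOB"])
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Select the top-k SNPs from an importance ranking
#'
#' `k` is a user choice: pick it by inspecting the sorted importance profile
#' (e.g. with [elbowK()] as a heuristic aid).
#'
#' @param ranking A ranking from [rfImportance()].
#' @param k Number of SNPs to keep, `1 <= k <= nrow(ranking)`.
#' @return Character vector of the first `k` SNP ids of the ranking.
#' @export
selectTopK <- function(ranking, k) {
  stopifnot(is.data.frame(ranking), "snp_id" %in% names(ranking))
  if (!.isCount(k) || k < 1 || k > nrow(ranking))
    stop("k must be an integer in [1, ", nrow(ranking), "]")
  ranking$snp_id[seq_len(k)]
}

#' Elbow heuristic for choosing k
#'
#' A labelled extension, not part of the core framework: returns the k at
#' the largest relative drop between consecutive sorted importances.
#'
#' @param ranking A ranking from [rfImportance()].
#' @return Suggested `k` (integer).
#' @export
elbowK <- function(ranking) {
  imp <- ranking$gini_importance
  if (length(imp) < 2) return(length(imp))
  prev <- imp[-length(imp)]
  drop <- (prev - imp[-1]) / pmax(prev, .Machine$double.eps)
  which.max(drop)
}
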