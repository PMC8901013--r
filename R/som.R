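#' SOMModel: a self-organizing map for nominal categorical genotypes
#'
#' A rectangular grid of units. Each unit holds, per SNP, a table of
#' accumulated category frequencies over the codes `{0,1,2,3}`, and its
#' prototype ("weight") is the mode vector derived from those frequencies
#' (argmax per SNP, ties to the smallest code). Distances between subjects
#' and units are Hamming distances on the code vectors, with the missing
#' code 0 treated as an ordinary fourth category.
#'
#' @slot gridRows,gridCols Grid dimensions.
#' @slot counts Numeric array `units x SNPs x 4` of accumulated category
#'   frequencies (categories = codes 0..3).
#' @slot modes Integer matrix `units x SNPs` of unit mode vectors.
#' @slot snpIds SNP ids the model was trained on (order matters).
#' @slot epochs,seed Training parameters.
#' @slot initialRadius Initial neighbourhood radius,
#'   `max(gridRows, gridCols) / 2`.
#' @seealso [trainSOM()], [assignClusters()]
#' @export
setClass("SOMModel", representation(
  gridRows = "integer", gridCols = "integer",
  counts = "array", modes = "matrix",
  snpIds = "character", epochs = "integer",
  initialRadius = "numeric", seed = "integer"
))

setValidity("SOMModel", function(object) {
  msg <- character()
  g <- object@gridRows * object@gridCols
  if (!all(dim(object@counts) == c(g, length(object@snpIds), 4L)))
    msg <- c(msg, "counts must be units x SNPs x 4")
  if (!all(dim(object@modes) == c(g, length(object@snpIds))))
    msg <- c(msg, "modes must be units x SNPs")
  if (length(object@modes) && !all(object@modes %in% 0:3))
    msg <- c(msg, "unit modes must be codes in {0,1,2,3}")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SOMModel", function(object) {
  cat("SOMModel: ", object@gridRows, "x", object@gridCols, " grid, ",
      length(object@snpIds), " SNPs, ", object@epochs, " epochs (seed ",
      object@seed, ")\n", sep = "")
})

#' Number of units of a SOM grid
#' @param model A [SOMModel-class].
#' @export
nUnits <- function(model) model@gridRows * model@gridCols

#' Unit mode vectors (prototypes) of a SOM
#' @param model A [SOMModel-class].
#' @return Integer matrix `units x SNPs`.
#' @export
unitModes <- function(model) model@modes

#' Hamming distance between two genotype code vectors
#'
#' Counts the positions at which the codes differ. The missing code 0 is an
#' ordinary fourth category: `(0,1)` vs `(1,1)` has distance 1.
#'
#' @param x,y Equal-length code vectors.
#' @return Integer count of differing positions.
#' @export
#' @examples
#' hammingDistance(c(1, 2, 3), c(3, 2, 1))  # 2
hammingDistance <- function(x, y) {
  if (length(x) != length(y))
    stop("length mismatch: ", length(x), " vs ", length(y))
  sum(x != y)
}

## subjects x units Hamming distance matrix (small unit counts; loop units)
.hammingToUnits <- function(X, modes) {
  n <- nrow(X)
  D <- matrix(0L, n, nrow(modes))
  for (u in seq_len(nrow(modes)))
    D[, u] <- rowSums(X != matrix(modes[u, ], n, ncol(X), byrow = TRUE))
  D
}

## Chebyshev distances between grid units (row-major unit indexing)
.gridDistances <- function(gridRows, gridCols) {
  rc <- cbind(rep(seq_len(gridRows), each = gridCols),
              rep(seq_len(gridCols), times = gridRows))
  g <- nrow(rc)
  D <- matrix(0L, g, g)
  for (u in seq_len(g))
    D[u, ] <- pmax(abs(rc[, 1] - rc[u, 1]), abs(rc[, 2] - rc[u, 2]))
  D
}

## BMU per subject with deterministic, subject-order-invariant tie-breaks:
## among tied units, the unit index is picked by the subject's genotype
## hash, which both breaks the symmetry that otherwise freezes the map when
## unit modes coincide and keeps training invariant to subject permutation.
.bmuTrain <- function(D, hash) {
  mins <- D == matrix(apply(D, 1, min), nrow(D), ncol(D))
  ntied <- rowSums(mins)
  bmu <- max.col(mins, ties.method = "first")
  tied <- which(ntied > 1L)
  for (i in tied) {
    cand <- which(mins[i, ])
    bmu[i] <- cand[(hash[i] %% length(cand)) + 1L]
  }
  bmu
}

.modesFromCounts <- function(counts, init) {
  g <- dim(counts)[1]; m <- dim(counts)[2]
  modes <- init
  for (u in seq_len(g)) {
    cu <- counts[u, , , drop = TRUE]
    if (m == 1L) cu <- matrix(cu, nrow = 1)
    touched <- rowSums(cu) > 0
    if (any(touched))
      # max.col(ties = "first") -> smallest code wins ties
      modes[u, touched] <- max.col(cu[touched, , drop = FALSE],
                                   ties.method = "first") - 1L
  }
  modes
}

#' Train a categorical self-organizing map
#'
#' A frequency-accumulation SOM for nominal data. Unit prototypes are
#' initialized from subject rows by farthest-point selection (the first
#' row is a seeded draw, each further unit takes the row maximizing its
#' minimum Hamming distance to the rows already chosen), computed on a
#' canonical subject ordering so training is invariant to subject order.
#' At each epoch the best-matching unit (BMU) of every subject is found by
#' minimum Hamming distance to the current unit modes; the subject's codes
#' are added to the category-frequency tables of the BMU (weight 1) and of
#' every unit within the current neighbourhood radius of it with weight
#' `0.5^d`, `d` the Chebyshev grid distance. The decaying neighbourhood
#' weight matters: a flat bubble weight makes every covered unit
#' accumulate identical frequencies whenever the radius spans the grid,
#' after which the argmax modes can never differentiate. The radius decays
#' linearly from `max(gridRows, gridCols)/2` to 0 over the epochs, and unit
#' modes are recomputed from the accumulated frequencies at each epoch end.
#' Frequencies are never reset, so the prototypes stabilize as evidence
#' accumulates; no learning rate is needed.
#'
#' @param x A [GenotypeExperiment-class].
#' @param gridRows,gridCols Grid dimensions; `gridRows * gridCols >= 2`.
#' @param epochs Training epochs (default 1000).
#' @param seed Integer seed (initialization is the only random element).
#' @return A [SOMModel-class].
#' @export
trainSOM <- function(x, gridRows, gridCols, epochs = 1000, seed = 1L) {
  stopifnot(is(x, "GenotypeExperiment"))
  X <- genotypes(x)
  X[is.na(X)] <- 0L   # binary encoding stores missing as NA
  if (!nrow(X) || !ncol(X)) stop("empty genotype matrix")
  gridRows <- as.integer(gridRows); gridCols <- as.integer(gridCols)
  g <- gridRows * gridCols
  if (g < 2) stop("grid must have at least 2 units")
  if (!.isCount(epochs) || epochs < 1) stop("epochs must be a count >= 1")
  epochs <- as.integer(epochs)

  hash <- .rowHash(X)
  ord <- order(hash, method = "radix")   # canonical subject order
  Xc <- X[ord, , drop = FALSE]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  ## farthest-point initialization on the canonical ordering
  pick <- sample.int(nrow(Xc), 1L)
  minD <- rowSums(Xc != matrix(Xc[pick, ], nrow(Xc), ncol(Xc),
                               byrow = TRUE))
  while (length(pick) < min(g, nrow(Xc))) {
    nxt <- which.max(minD)   # ties -> first in canonical order
    pick <- c(pick, nxt)
    minD <- pmin(minD, rowSums(Xc != matrix(Xc[nxt, ], nrow(Xc), ncol(Xc),
                                            byrow = TRUE)))
  }
  if (length(pick) < g) pick <- rep_len(pick, g)
  modes <- Xc[pick, , drop = FALSE]
  dimnames(modes) <- NULL

  counts <- array(0, dim = c(g, ncol(X), 4L))
  gridD <- .gridDistances(gridRows, gridCols)
  r0 <- max(gridRows, gridCols) / 2

  for (e in seq_len(epochs)) {
    radius <- r0 * (1 - (e - 1) / epochs)
    D <- .hammingToUnits(X, modes)
    bmu <- .bmuTrain(D, hash)
    for (u in seq_len(g)) {
      dvals <- unique(gridD[, u])
      for (d in dvals[dvals <= radius]) {
        members <- which(gridD[bmu, u] == d)
        if (!length(members)) next
        w <- 0.5^d
        for (s in seq_len(ncol(X)))
          counts[u, s, ] <- counts[u, s, ] +
            w * tabulate(X[members, s] + 1L, nbins = 4L)
      }
    }
    modes <- .modesFromCounts(counts, modes)
  }

  new("SOMModel", gridRows = gridRows, gridCols = gridCols,
      counts = counts, modes = modes, snpIds = snpIds(x),
      epochs = epochs, initialRadius = r0, seed = as.integer(seed))
}

#' Assign subjects to SOM units
#'
#' Each subject is mapped to its best-matching unit (minimum Hamming
#' distance to the unit modes); ties go to the smallest unit index.
#'
#' @param model A [SOMModel-class].
#' @param x A [GenotypeExperiment-class] with the same SNPs, same order.
#' @return Integer vector of unit (cluster) ids, one per subject, named by
#'   subject id.
#' @export
assignClusters <- function(model, x) {
  stopifnot(is(model, "SOMModel"), is(x, "GenotypeExperiment"))
  if (!identical(model@snpIds, snpIds(x)))
    stop("SNP ids/order of the data do not match the model")
  X <- genotypes(x)
  X[is.na(X)] <- 0L
  D <- .hammingToUnits(X, model@modes)
  ids <- max.col(-D, ties.method = "first")
  names(ids) <- subjectIds(x)
  ids
}

#' Pearson chi-square test on a contingency table
#'
#' The shared kernel for cluster evaluation and the interaction
#' decomposition. All-zero rows and columns are dropped before computing
#' `sum((O - E)^2 / E)` with expectations from the margins;
#' `df = (rows - 1) * (cols - 1)` on the retained table. A table with fewer
#' than two non-empty rows or columns is degenerate: `(statistic = 0,
#' df = 0, degenerate = TRUE)`.
#'
#' @param table Matrix of non-negative counts.
#' @return A list with `statistic`, `df`, `degenerate`.
#' @export
#' @examples
#' pearsonChi2(rbind(c(40, 10), c(10, 40)))  # statistic 36, df 1
pearsonChi2 <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || anyNA(tab)) stop("counts must be non-negative")
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    return(list(statistic = 0, df = 0L, degenerate = TRUE))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(statistic = sum((tab - E)^2 / E),
       df = (nrow(tab) - 1L) * (ncol(tab) - 1L),
       degenerate = FALSE)
}

#' Evaluate a clustering against the phenotype
#'
#' Pearson chi-square test on the clusters-by-\{cases, controls\}
#' contingency table; empty clusters are dropped.
#'
#' @param assignments Cluster ids per subject (from [assignClusters()]).
#' @param labels Phenotype factor (levels control, case) or a
#'   [GenotypeExperiment-class].
#' @return A list with `contingency` (clusters x c(cases, controls)),
#'   `statistic`, `df`, `p_value`, and `applicable` (`FALSE` when fewer than
#'   two non-empty clusters, in which case `p_value` is `NA`).
#' @export
evaluateClustering <- function(assignments, labels) {
  if (is(labels, "SummarizedExperiment")) labels <- phenotype(labels)
  stopifnot(length(assignments) == length(labels))
  cl <- sort(unique(assignments))
  tab <- cbind(
    cases = vapply(cl, function(k) sum(assignments == k & labels == "case"),
                   numeric(1)),
    controls = vapply(cl, function(k)
      sum(assignments == k & labels == "control"), numeric(1))
  )
  rownames(tab) <- cl
  if (nrow(tab) < 2)
    return(list(contingency = tab, statistic = NA_real_, df = 0L,
                p_value = NA_real_, applicable = FALSE))
  p <- pearsonChi2(tab)
  pv <- if (p$degenerate) NA_real_ else
    pchisq(p$statistic, p$df, lower.tail = FALSE)
  list(contingency = tab, statistic = p$statistic, df = p$df,
       p_value = pv, applicable = !p$degenerate)
}

#' Select a SOM map size by cross-validated chi-square evaluation
#'
#' For each candidate grid size, a stratified k-fold split is repeated
#' `repeats` times with fresh seeds; per fold the SOM is trained on the
#' training portion, both portions are assigned, and the clustering is
#' evaluated ([evaluateClustering()]) on each. The selection criterion is
#' the median *test* p-value across all folds and repeats (degenerate
#' evaluations count as p = 1); the size with the lowest median test
#' p-value wins, ties going to the smaller unit count and then to candidate
#' order. The caller should proceed to retrain on all data only when the
#' winning p-value passes the significance gate (<= 0.05 by convention).
#'
#' @param x A [GenotypeExperiment-class].
#' @param candidateSizes List of `c(rows, cols)` pairs. Default
#'   `list(c(1,2), c(2,2), c(2,3), c(3,3), c(3,4), c(4,4))`.
#' @param kFolds Folds of the stratified split (default 2).
#' @param repeats Seeded repetitions (default 10).
#' @param epochs Training epochs per fit (default 1000).
#' @param seed Integer seed.
#' @return A list with `best_size` (`c(rows, cols)`), `best_p` (its median
#'   test p-value) and `table` (a data.frame per size: `rows`, `cols`,
#'   `median_test_p`, `median_train_p`).
#' @export
selectMapSize <- function(x, candidateSizes = NULL, kFolds = 2, repeats = 10,
                          epochs = 1000, seed = 1L) {
  stopifnot(is(x, "GenotypeExperiment"))
  if (is.null(candidateSizes))
    candidateSizes <- list(c(1, 2), c(2, 2), c(2, 3), c(3, 3), c(3, 4),
                           c(4, 4))
  if (!length(candidateSizes)) stop("candidateSizes must be non-empty")
  if (!.isCount(kFolds) || kFolds < 2) stop("kFolds must be >= 2")
  ph <- phenotype(x)
  .checkBothClasses(ph)
  folds <- .stratifiedFolds(ph, kFolds, repeats,
                            deriveSeed(seed, "map-cv-folds"))
  testP <- trainP <- matrix(NA_real_, length(candidateSizes),
                            kFolds * repeats)
  for (si in seq_along(candidateSizes)) {
    sz <- candidateSizes[[si]]
    col <- 0L
    for (r in seq_len(repeats)) {
      for (f in seq_len(kFolds)) {
        col <- col + 1L
        trainIdx <- which(folds[, r] != f)
        testIdx <- which(folds[, r] == f)
        if (length(unique(ph[trainIdx])) < 2 ||
            length(unique(ph[testIdx])) < 2)
          stop("a CV fold is missing a phenotype class; reduce kFolds")
        fitSeed <- deriveSeed(seed, sprintf("map-cv-%dx%d-r%d-f%d",
                                            sz[1], sz[2], r, f))
        model <- trainSOM(x[, trainIdx], sz[1], sz[2], epochs = epochs,
                          seed = fitSeed)
        evTr <- evaluateClustering(assignClusters(model, x[, trainIdx]),
                                   ph[trainIdx])
        evTe <- evaluateClustering(assignClusters(model, x[, testIdx]),
                                   ph[testIdx])
        trainP[si, col] <- if (evTr$applicable) evTr$p_value else 1
        testP[si, col] <- if (evTe$applicable) evTe$p_value else 1
      }
    }
  }
  tab <- data.frame(
    rows = vapply(candidateSizes, `[`, numeric(1), 1),
    cols = vapply(candidateSizes, `[`, numeric(1), 2),
    median_test_p = apply(testP, 1, median),
    median_train_p = apply(trainP, 1, median)
  )
  o <- order(tab$median_test_p, tab$rows * tab$cols,
             seq_len(nrow(tab)))[1]
  list(best_size = c(tab$rows[o], tab$cols[o]),
       best_p = tab$median_test_p[o], table = tab)
}

## subjects x repeats matrix of fold ids, stratified by class
.stratifiedFolds <- function(ph, kFolds, repeats, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- matrix(0L, length(ph), repeats)
  for (r in seq_len(repeats)) {
    for (lv in levels(ph)) {
      idx <- which(ph == lv)
      if (length(idx) < kFolds)
        stop("class '", lv, "' has fewer subjects than folds")
      out[sample(idx), r] <- rep_len(seq_len(kFolds), length(idx))
    }
  }
  out
}

#' Summarize SOM clusters: sizes, majority label, member modes
#'
#' Per non-empty cluster, counts cases and controls, assigns the majority
#' label (a tie is labelled with the overall minority class and flagged),
#' and recomputes the per-SNP most frequent genotype *from the member
#' subjects* (not from the unit's training-time prototype). Missing codes
#' are excluded from the member mode unless a SNP is missing in every
#' member, in which case the mode is 0.
#'
#' @param assignments Cluster ids from [assignClusters()].
#' @param x The assigned [GenotypeExperiment-class].
#' @param selectedSnps Optional subset of SNP ids to report modes for
#'   (default: all).
#' @return A data.frame with one row per non-empty cluster: `cluster_id`,
#'   `n_cases`, `n_controls`, `majority_label`, `tie`, then one `mode_<snp>`
#'   column per reported SNP.
#' @export
summarizeClusters <- function(assignments, x, selectedSnps = NULL) {
  stopifnot(is(x, "GenotypeExperiment"),
            length(assignments) == ncol(x))
  ph <- phenotype(x)
  g <- genotypes(x)
  if (is.null(selectedSnps)) selectedSnps <- snpIds(x)
  stopifnot(all(selectedSnps %in% snpIds(x)))
  overallMinority <- if (sum(ph == "case") <= sum(ph == "control"))
    "cases" else "controls"
  cl <- sort(unique(assignments))
  rows <- lapply(cl, function(k) {
    member <- assignments == k
    nca <- sum(member & ph == "case"); nco <- sum(member & ph == "control")
    tie <- nca == nco
    maj <- if (tie) overallMinority else if (nca > nco) "cases" else "controls"
    initial <- genotypeEncoding(x) == "initial"
    modes <- vapply(selectedSnps, function(s) {
      v <- g[member, s]
      v <- v[!is.na(v)]
      if (initial) v <- v[v != 0L]   # code 0 is missing only here
      if (!length(v)) return(0L)
      tb <- tabulate(v + 1L, nbins = 4L)
      as.integer(which.max(tb) - 1L)   # ties -> smallest code
    }, integer(1))
    c(list(cluster_id = k, n_cases = nca, n_controls = nco,
           majority_label = maj, tie = tie),
      as.list(stats::setNames(modes, paste0("mode_", selectedSnps))))
  })
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Choose the reference cluster for binary encoding
#'
#' Default policy: among the clusters whose majority label is the label
#' held by fewer clusters overall (e.g. the single controls-majority
#' cluster of a map otherwise dominated by cases clusters), pick the one
#' maximizing `|cluster case-fraction - overall case-fraction| * size`;
#' ties go to the larger cluster, then the smaller id. An explicit
#' `override` always wins.
#'
#' @param summaries A data.frame from [summarizeClusters()].
#' @param override Optional cluster id to force.
#' @return The selected `cluster_id`.
#' @export
chooseReferenceCluster <- function(summaries, override = NULL) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1)
  if (!is.null(override)) {
    if (!override %in% summaries$cluster_id)
      stop("override cluster ", override, " does not exist")
    return(override)
  }
  labCounts <- table(factor(summaries$majority_label,
                            levels = c("cases", "controls")))
  if (any(labCounts == 0))
    stop("no cluster matches the reference policy (all clusters have ",
         "majority '", names(labCounts)[labCounts > 0][1],
         "'); choose one explicitly with override=")
  minorityLab <- if (labCounts["cases"] != labCounts["controls"])
    names(labCounts)[which.min(labCounts)]
  else if (sum(summaries$n_cases) <= sum(summaries$n_controls)) "cases"
  else "controls"   # equal cluster counts: fall back to the rarer class
  cand <- summaries[summaries$majority_label == minorityLab, , drop = FALSE]
  size <- cand$n_cases + cand$n_controls
  overallCaseFrac <- sum(summaries$n_cases) /
    sum(summaries$n_cases + summaries$n_controls)
  score <- abs(cand$n_cases / size - overallCaseFrac) * size
  o <- order(-score, -size, cand$cluster_id)[1]
  cand$cluster_id[o]
}

#' Extract a reference cluster's per-SNP modes
#'
#' @param summaries A data.frame from [summarizeClusters()].
#' @param clusterId The reference cluster id.
#' @return Named integer vector of mode codes per SNP.
#' @export
referenceModes <- function(summaries, clusterId) {
  row <- summaries[summaries$cluster_id == clusterId, , drop = FALSE]
  if (nrow(row) != 1) stop("cluster ", clusterId, " not found")
  modeCols <- grep("^mode_", names(summaries), value = TRUE)
  stats::setNames(as.integer(row[1, modeCols]),
                  sub("^mode_", "", modeCols))
}

#' Binary-encode genotypes against a reference cluster's modes
#'
#' Per SNP, the genotype equal to the reference cluster's mode becomes 1,
#' every other observed genotype becomes 0, and missing stays missing
#' (`NA` in the binary encoding). Applied to all subjects: the downstream
#' interaction tests then ask whether *carrying the reference-cluster
#' genotype pattern* at several loci jointly separates cases from controls,
#' with 1 degree of freedom per SNP instead of 2.
#'
#' @param x A [GenotypeExperiment-class] (initial encoding).
#' @param reference Named integer vector of mode codes per SNP (from
#'   [referenceModes()]), covering every SNP of `x` with codes in
#'   `{1,2,3}`.
#' @return A binary-encoding [GenotypeExperiment-class].
#' @export
binarizeMatrix <- function(x, reference) {
  stopifnot(is(x, "GenotypeExperiment"))
  ids <- snpIds(x)
  if (!all(ids %in% names(reference)))
    stop("reference modes missing for SNP(s): ",
         paste(setdiff(ids, names(reference)), collapse = ", "))
  ref <- reference[ids]
  if (any(is.na(ref) | !(ref %in% 1:3)))
    stop("reference mode must be a genotype code in {1,2,3} for every SNP")
  g <- genotypes(x)
  initial <- genotypeEncoding(x) == "initial"
  bin <- matrix(NA_integer_, nrow(g), ncol(g), dimnames = dimnames(g))
  for (j in seq_along(ids)) {
    v <- g[, j]
    miss <- is.na(v) | (initial & v == 0L)
    bin[, j] <- ifelse(miss, NA_integer_, as.integer(v == ref[j]))
  }
  GenotypeExperiment(bin, phenotype(x), snpIds = ids,
                     subjectIds = subjectIds(x), geneLabels = geneLabels(x),
                     phenotypeCoding = "labels", encoding = "binary")
}
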