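#' Build a pipeline configuration
#'
#' All knobs of the four-step framework in one validated list. Defaults
#' follow the package's standard analysis: QC at 5% missingness / 5% MAF
#' (HWE off), a 50-tree Random Forest, SOM map-size selection by
#' stratified 2-fold CV repeated 10 times at 1000 epochs, a clustering
#' significance gate at p <= 0.05, and exhaustive order-\{2,3\} scans with
#' both methods on both encodings, adjusted by 10,000 max-T permutations.
#'
#' @param input Path to a genotype table, or a
#'   [GenotypeExperiment-class] passed directly to [runPipeline()].
#' @param format,phenotypeColumn,idColumn,phenotypeCoding Reader options,
#'   see [readGenotypeTable()].
#' @param missingMax,mafMin,hweAlpha QC thresholds ([applyQC()]).
#' @param nTrees,topK Feature selection ([rfImportance()]); `topK` is
#'   required.
#' @param mapSizes,epochs,cvFolds,cvRepeats,clusterAlpha,referenceCluster
#'   Clustering options ([selectMapSize()], [chooseReferenceCluster()]).
#' @param orders,methods,encodings,nPermutations,adjust,alpha Scan options.
#' @param force Proceed past a failed clustering gate (logged).
#' @param seed Global seed; every stage derives its own via
#'   [deriveSeed()].
#' @param outDir Output directory for TSV artifacts, or `NULL` to skip
#'   writing.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(input = NULL, format = "csv",
                           phenotypeColumn = "phenotype", idColumn = NULL,
                           phenotypeCoding = "auto",
                           missingMax = 0.05, mafMin = 0.05,
                           hweAlpha = NULL,
                           nTrees = 50, topK = NULL,
                           mapSizes = NULL, epochs = 1000,
                           cvFolds = 2, cvRepeats = 10,
                           clusterAlpha = 0.05, referenceCluster = NULL,
                           orders = c(2, 3),
                           methods = c("logistic", "chi2"),
                           encodings = c("initial", "binary"),
                           nPermutations = 10000,
                           adjust = "max_t", alpha = 0.05,
                           force = FALSE, seed = 1L, outDir = NULL) {
  stopifnot(alpha > 0, alpha < 1, clusterAlpha > 0, clusterAlpha < 1,
            all(orders %in% 2:3),
            all(methods %in% c("logistic", "chi2")),
            all(encodings %in% c("initial", "binary")))
  if (is.null(topK)) stop("topK must be set (choose it from the ",
                          "importance profile)")
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipelineConfig()]; `map_sizes` may be a
#' list of `[rows, cols]` pairs. Unknown keys raise an error.
#'
#' @param path YAML file path.
#' @param ... Overrides applied on top of the file (CLI flags win).
#' @return A `PipelineConfig`.
#' @export
readPipelineConfig <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  names(raw) <- gsub("_(.)", "\\U\\1", names(raw), perl = TRUE)
  if ("mapSizes" %in% names(raw))
    raw$mapSizes <- lapply(raw$mapSizes, as.numeric)
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  unknown <- setdiff(names(raw), names(formals(pipelineConfig)))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, raw)
}

.pipelineLog <- function(report, stage, msg) {
  line <- paste0("[", stage, "] ", msg)
  message(line)
  c(report, line)
}

#' Run the four-step framework end-to-end
#'
#' QC, Random-Forest feature selection, SOM map-size selection (with the
#' significance gate: the analysis proceeds only when the best
#' cross-validated clustering p-value is <= `clusterAlpha`, unless
#' `force`), full-data SOM + cluster summary + reference-cluster choice +
#' binary encoding, then exhaustive scans per method and encoding with
#' permutation adjustment and a final comparison table. All artifacts are
#' written to `outDir` (when set) as TSVs via [writeResultsTable()],
#' together with a config/seed snapshot.
#'
#' @param config A [pipelineConfig()].
#' @param x Optional [GenotypeExperiment-class]; when `NULL` the input is
#'   read from `config$input`.
#' @return A list of class `PipelineRun`: `qc` (report), `importance`,
#'   `selected` (SNP ids), `map_selection`, `gate_passed`, and, when the
#'   gate passes, `model`, `assignments`, `cluster_evaluation`,
#'   `clusters`, `reference_cluster`, `scans` (named
#'   `<method>_<encoding>` data.frames), `comparison`, `n_tests`, `log`.
#' @export
runPipeline <- function(config, x = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  log <- character()
  if (is.null(x)) {
    if (is(config$input, "GenotypeExperiment")) x <- config$input
    else x <- readGenotypeTable(config$input, format = config$format,
                                phenotypeColumn = config$phenotypeColumn,
                                idColumn = config$idColumn,
                                phenotypeCoding = config$phenotypeCoding)
  }
  out <- list(config = config, seed = config$seed)
  dirOut <- config$outDir
  if (!is.null(dirOut) && !dir.exists(dirOut))
    dir.create(dirOut, recursive = TRUE)
  emit <- function(df, name) {
    if (!is.null(dirOut))
      writeResultsTable(df, file.path(dirOut, paste0(name, ".tsv")))
  }
  log <- .pipelineLog(log, "input", sprintf(
    "%d subjects (%d cases / %d controls), %d SNPs", ncol(x),
    sum(phenotype(x) == "case"), sum(phenotype(x) == "control"), nrow(x)))

  ## step 1: QC
  qc <- applyQC(x, missingMax = config$missingMax, mafMin = config$mafMin,
                hweAlpha = config$hweAlpha)
  out$qc <- qc$report
  emit(qc$report, "qc_report")
  log <- .pipelineLog(log, "qc", sprintf(
    "%d SNPs failed missingness, %d more failed MAF%s; %d retained",
    sum(!qc$report$pass_missing),
    sum(qc$report$pass_missing & !qc$report$pass_maf),
    if (!is.null(config$hweAlpha))
      sprintf(", %d more failed HWE",
              sum(qc$report$pass_missing & qc$report$pass_maf &
                  !qc$report$pass_hwe)) else "",
    sum(qc$report$pass)))
  xq <- qc$genotypes

  ## step 2: feature selection
  ranking <- rfImportance(xq, nTrees = config$nTrees,
                          seed = deriveSeed(config$seed, "rf"))
  out$importance <- ranking
  emit(ranking, "importance")
  selected <- selectTopK(ranking, config$topK)
  out$selected <- selected
  log <- .pipelineLog(log, "select", sprintf(
    "top %d SNPs by Gini importance (OOB error %.3f): %s", config$topK,
    attr(ranking, "oob_error"), paste(selected, collapse = ", ")))
  xs <- xq[selected, ]

  ## step 3: clustering with map-size selection and significance gate
  ms <- selectMapSize(xs, candidateSizes = config$mapSizes,
                      kFolds = config$cvFolds, repeats = config$cvRepeats,
                      epochs = config$epochs,
                      seed = deriveSeed(config$seed, "map-cv"))
  out$map_selection <- ms$table
  emit(ms$table, "map_selection")
  log <- .pipelineLog(log, "cluster", sprintf(
    "selected %dx%d map (median CV test p = %.3g)", ms$best_size[1],
    ms$best_size[2], ms$best_p))
  out$gate_passed <- ms$best_p <= config$clusterAlpha
  if (!out$gate_passed && !config$force) {
    log <- .pipelineLog(log, "cluster", sprintf(
      "gate failed (p = %.3g > %.2f); stopping before interaction testing",
      ms$best_p, config$clusterAlpha))
    out$log <- log
    class(out) <- "PipelineRun"
    return(out)
  }
  if (!out$gate_passed)
    log <- .pipelineLog(log, "cluster",
                        "gate failed but --force set; PROCEEDING anyway")

  model <- trainSOM(xs, ms$best_size[1], ms$best_size[2],
                    epochs = config$epochs,
                    seed = deriveSeed(config$seed, "som-final"))
  assignments <- assignClusters(model, xs)
  ev <- evaluateClustering(assignments, phenotype(xs))
  out$model <- model
  out$assignments <- assignments
  out$cluster_evaluation <- ev
  log <- .pipelineLog(log, "cluster", sprintf(
    "full-data clustering: %d clusters, chi2 = %.2f (df %d), p = %.3g",
    nrow(ev$contingency), ev$statistic, ev$df, ev$p_value))
  clusters <- summarizeClusters(assignments, xs)
  out$clusters <- clusters
  emit(clusters, "clusters")

  ## step 4: binary encoding + scans
  refId <- chooseReferenceCluster(clusters,
                                  override = config$referenceCluster)
  out$reference_cluster <- refId
  log <- .pipelineLog(log, "encode", sprintf(
    "reference cluster %s (%s-majority); binary encoding derived from its modes",
    refId, clusters$majority_label[clusters$cluster_id == refId]))
  xbin <- binarizeMatrix(xs, referenceModes(clusters, refId))
  enc <- list(initial = xs, binary = xbin)

  scans <- list()
  for (method in config$methods) {
    for (encoding in config$encodings) {
      pieces <- lapply(config$orders, function(o)
        exhaustiveScan(enc[[encoding]], order = o, method = method))
      sc <- do.call(rbind, pieces)
      attr(sc, "method") <- method
      attr(sc, "encoding") <- encoding
      attr(sc, "coding") <- "as_is"
      sc <- permutationAdjust(enc[[encoding]], sc,
                              nPermutations = config$nPermutations,
                              adjust = config$adjust,
                              seed = deriveSeed(config$seed,
                                                "permutations"))
      key <- paste(method, encoding, sep = "_")
      scans[[key]] <- sc
      emit(sc, paste0("scan_", key))
      log <- .pipelineLog(log, "scan", sprintf(
        "%s / %s: %d tuples, %d significant (adjusted p < %.2f)", method,
        encoding, nrow(sc),
        sum(sc$p_adjusted < config$alpha, na.rm = TRUE), config$alpha))
    }
  }
  out$scans <- scans
  out$n_tests <- countTotalTests(length(selected), config$orders,
                                 config$nPermutations)
  log <- .pipelineLog(log, "scan", sprintf(
    "total statistical evaluations: %s",
    format(out$n_tests, big.mark = ",", scientific = FALSE)))

  if (all(c("initial", "binary") %in% config$encodings)) {
    comp <- list()
    for (method in config$methods) {
      comp[[method]] <- compareEncodings(
        scans[[paste0(method, "_initial")]],
        scans[[paste0(method, "_binary")]], alpha = config$alpha)
    }
    out$comparison <- do.call(rbind, comp)
    rownames(out$comparison) <- NULL
    emit(out$comparison, "comparison")
  }
  if (!is.null(dirOut)) {
    snapshot <- config
    snapshot$input <- if (is.character(config$input)) config$input
                      else "<in-memory GenotypeExperiment>"
    writeLines(yaml::as.yaml(lapply(snapshot, function(v)
      if (is.null(v)) "null" else v)), file.path(dirOut, "config.yaml"))
    writeLines(log, file.path(dirOut, "run.log"))
  }
  out$log <- log
  class(out) <- "PipelineRun"
  out
}

#' Compare scan significance between encodings
#'
#' Per tuple and method: was the tuple significant (adjusted p < alpha)
#' under the initial and/or the binary encoding?
#'
#' @param scanInitial,scanBinary Adjusted scan data.frames over the same
#'   tuples and method.
#' @param alpha Significance level (default 0.05).
#' @return A data.frame with `snp1..snp3`, `method`,
#'   `sig_initial`, `sig_binary`, plus attributes `n_sig_initial`,
#'   `n_sig_binary`.
#' @export
compareEncodings <- function(scanInitial, scanBinary, alpha = 0.05) {
  key <- function(df) paste(df$snp1, df$snp2, df$snp3, df$method, sep = "|")
  if (!setequal(key(scanInitial), key(scanBinary)))
    stop("the two scans cover different tuples/methods")
  b <- scanBinary[match(key(scanInitial), key(scanBinary)), ]
  out <- data.frame(
    snp1 = scanInitial$snp1, snp2 = scanInitial$snp2,
    snp3 = scanInitial$snp3, method = scanInitial$method,
    sig_initial = !is.na(scanInitial$p_adjusted) &
      scanInitial$p_adjusted < alpha,
    sig_binary = !is.na(b$p_adjusted) & b$p_adjusted < alpha,
    stringsAsFactors = FALSE)
  attr(out, "n_sig_initial") <- sum(out$sig_initial)
  attr(out, "n_sig_binary") <- sum(out$sig_binary)
  out
}
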