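#' Chi2InteractionResult: one chi-square interaction test
#'
#' Holds the component statistics and degrees of freedom of the
#' decomposition
#' \deqn{\chi^2_{A*B} = \chi^2_{A+B} - \chi^2_A - \chi^2_B}
#' (and its 3-SNP extension subtracting the three pairwise interactions and
#' the three main effects from the omnibus joint term), with df composed
#' the same way from the realized table dimensions. The reference
#' chi-square distribution requires a non-negative statistic, so a negative
#' difference is truncated at 0 for the p-value; the signed value is kept
#' in `rawStat`.
#'
#' @slot snpTuple The 2 or 3 SNP ids.
#' @slot encoding `"initial"` or `"binary"`.
#' @slot chi2Terms,dfTerms Named component statistics / df (mains, joint
#'   terms, and for 3 SNPs the pairwise interaction terms).
#' @slot interactionStat Truncated (>= 0) interaction statistic.
#' @slot rawStat Signed interaction statistic.
#' @slot interactionDf Interaction degrees of freedom (composition of the
#'   realized df terms).
#' @slot nUsed Subjects remaining after pairwise deletion.
#' @slot pRaw Upper-tail p-value (NA when untestable).
#' @slot testable `FALSE` when `interactionDf < 1`.
#' @export
setClass("Chi2InteractionResult", representation(
  snpTuple = "character", encoding = "character",
  chi2Terms = "numeric", dfTerms = "integer",
  interactionStat = "numeric", rawStat = "numeric",
  interactionDf = "integer", nUsed = "integer",
  pRaw = "numeric", testable = "logical"))

setMethod("show", "Chi2InteractionResult", function(object) {
  cat("Chi-square interaction test: ",
      paste(object@snpTuple, collapse = " x "),
      " (", object@encoding, " encoding, n = ", object@nUsed, ")\n",
      sep = "")
  if (object@testable)
    cat(sprintf("  statistic = %.4f on %d df, p = %.4g\n",
                object@interactionStat, object@interactionDf, object@pRaw))
  else cat("  untestable (interaction df < 1)\n")
})

#' @describeIn Chi2InteractionResult-class Named component chi-square terms.
#' @param object A `Chi2InteractionResult`.
#' @export
chi2Terms <- function(object) object@chi2Terms

#' @describeIn Chi2InteractionResult-class Named component df terms.
#' @export
dfTerms <- function(object) object@dfTerms

#' @describeIn Chi2InteractionResult-class Interaction statistic (truncated
#'   at 0).
#' @export
interactionStat <- function(object) object@interactionStat

#' @describeIn Chi2InteractionResult-class Interaction degrees of freedom.
#' @export
interactionDf <- function(object) object@interactionDf

#' @describeIn Chi2InteractionResult-class Raw p-value.
#' @export
pRaw <- function(object) object@pRaw

#' LogisticInteractionFit: one logistic interaction model
#'
#' Maximum-likelihood fit of the saturated product-term logistic model
#' (`~ x_A * x_B`, or the triple-product model for 3 SNPs) on the numeric
#' values of the current encoding. Significance of the interaction is the
#' two-sided Wald test of the highest-order coefficient.
#'
#' @slot snpTuple,encoding As in [Chi2InteractionResult-class].
#' @slot coefficients,se Named coefficient estimates and standard errors.
#' @slot interactionP Wald p-value of the highest-order term (NA when the
#'   fit is not usable).
#' @slot nUsed Subjects after pairwise deletion.
#' @slot converged,separation,testable Fit diagnostics; `testable` is
#'   `FALSE` for constant predictors / singular information.
#' @export
setClass("LogisticInteractionFit", representation(
  snpTuple = "character", encoding = "character",
  coefficients = "numeric", se = "numeric",
  interactionP = "numeric", nUsed = "integer",
  converged = "logical", separation = "logical", testable = "logical"))

setMethod("show", "LogisticInteractionFit", function(object) {
  cat("Logistic interaction fit: ",
      paste(object@snpTuple, collapse = " x "),
      " (", object@encoding, " encoding, n = ", object@nUsed, ")\n",
      sep = "")
  if (object@testable && !is.na(object@interactionP)) {
    k <- length(object@coefficients)
    cat(sprintf("  %s = %.4f (se %.4f), Wald p = %.4g\n",
                names(object@coefficients)[k], object@coefficients[k],
                object@se[k], object@interactionP))
  } else cat("  untestable (constant predictor, separation, or no ",
             "convergence)\n", sep = "")
})

#' @describeIn LogisticInteractionFit-class Wald p-value of the
#'   highest-order coefficient.
#' @param object A `LogisticInteractionFit`.
#' @export
interactionP <- function(object) object@interactionP

## ---- internal tuple preparation ---------------------------------------

.genoValues <- function(x) {
  g <- genotypes(x)
  if (genotypeEncoding(x) == "initial") g[g == 0L] <- NA_integer_
  g
}

## pairwise deletion + margin construction for the chi2 kernel
.prepChi2Tuple <- function(vals, cols) {
  sub <- which(stats::complete.cases(vals[, cols, drop = FALSE]))
  k <- length(cols)
  if (!length(sub))
    return(list(subj = integer(0), order = k, margins = list(), m = integer(0),
                n = 0L))
  cc <- vals[sub, cols, drop = FALSE]
  f <- vector("list", k)
  L <- integer(k)
  for (j in seq_len(k)) {
    u <- sort(unique(cc[, j]))
    f[[j]] <- match(cc[, j], u) - 1L
    L[j] <- length(u)
  }
  comb <- function(js) {
    idx <- f[[js[1]]]
    mult <- L[js[1]]
    for (j in js[-1]) {
      idx <- idx + mult * f[[j]]
      mult <- mult * L[j]
    }
    list(idx = idx, m = mult)
  }
  if (k == 2L) {
    ms <- list(f[[1]], f[[2]], comb(c(1, 2))$idx)
    m <- c(L[1], L[2], comb(c(1, 2))$m)
    nm <- c("A", "B", "A+B")
  } else {
    cAB <- comb(c(1, 2)); cBC <- comb(c(2, 3)); cAC <- comb(c(1, 3))
    cABC <- comb(c(1, 2, 3))
    ms <- list(f[[1]], f[[2]], f[[3]], cAB$idx, cBC$idx, cAC$idx, cABC$idx)
    m <- c(L, cAB$m, cBC$m, cAC$m, cABC$m)
    nm <- c("A", "B", "C", "A+B", "B+C", "A+C", "A+B+C")
  }
  list(subj = sub - 1L, order = k, margins = ms, m = as.integer(m),
       names = nm, n = length(sub))
}

## pairwise deletion + model matrix for the logistic kernel
.prepLogisticTuple <- function(vals, cols, encoding,
                               coding = c("as_is", "centered")) {
  coding <- match.arg(coding)
  sub <- which(stats::complete.cases(vals[, cols, drop = FALSE]))
  k <- length(cols)
  if (!length(sub))
    return(list(subj = integer(0), X = matrix(0, 0, 0), n = 0L,
                testable = FALSE))
  cc <- vals[sub, cols, drop = FALSE]
  storage.mode(cc) <- "double"
  if (encoding == "initial" && coding == "centered") cc <- cc - 1
  nm <- c("A", "B", "C")[seq_len(k)]
  if (k == 2L) {
    X <- cbind(1, cc[, 1], cc[, 2], cc[, 1] * cc[, 2])
    colnames(X) <- c("(Intercept)", "beta_A", "beta_B", "beta_AB")
  } else {
    X <- cbind(1, cc[, 1], cc[, 2], cc[, 3],
               cc[, 1] * cc[, 2], cc[, 1] * cc[, 3], cc[, 2] * cc[, 3],
               cc[, 1] * cc[, 2] * cc[, 3])
    colnames(X) <- c("(Intercept)", "beta_A", "beta_B", "beta_C",
                     "beta_AB", "beta_AC", "beta_BC", "beta_ABC")
  }
  constant <- apply(X[, -1, drop = FALSE], 2, function(v)
    max(v) == min(v))
  list(subj = sub - 1L, X = X, n = length(sub), testable = !any(constant))
}

.resolveSnps <- function(x, snps) {
  if (is.numeric(snps)) snps <- snpIds(x)[snps]
  if (!all(snps %in% snpIds(x)))
    stop("unknown SNP id(s): ", paste(setdiff(snps, snpIds(x)),
                                      collapse = ", "))
  if (!length(snps) %in% 2:3) stop("need 2 or 3 SNPs")
  snps
}

#' Chi-square interaction test for a pair or triple of SNPs
#'
#' Subjects missing a genotype in any of the tuple's SNPs are removed
#' first (pairwise deletion); each component statistic is then a Pearson
#' chi-square of a genotype margin (single SNP, or the joint
#' genotype-combination variable with one row per observed combination)
#' against case/control status, and the interaction statistic and df are
#' the decomposition described in [Chi2InteractionResult-class].
#'
#' @param x A [GenotypeExperiment-class] (either encoding).
#' @param snps 2 or 3 SNP ids (or indices).
#' @return A [Chi2InteractionResult-class].
#' @export
chi2Interaction <- function(x, snps) {
  stopifnot(is(x, "GenotypeExperiment"))
  snps <- .resolveSnps(x, snps)
  .checkBothClasses(phenotype(x))
  vals <- .genoValues(x)
  prep <- .prepChi2Tuple(vals, snps)
  if (prep$n == 0L) stop("no subject has complete genotypes for tuple ",
                         paste(snps, collapse = ", "))
  y <- as.integer(phenotype(x) == "case")[prep$subj + 1L]
  res <- .chi2DecomposeCpp(prep, y)
  .chi2Result(snps, genotypeEncoding(x), prep, res)
}

.chi2Result <- function(snps, encoding, prep, res) {
  terms <- stats::setNames(res$term_stats, prep$names)
  dfs <- stats::setNames(as.integer(res$term_dfs), prep$names)
  if (prep$order == 3L) {
    pair <- c("A*B" = unname(terms["A+B"] - terms["A"] - terms["B"]),
              "B*C" = unname(terms["B+C"] - terms["B"] - terms["C"]),
              "A*C" = unname(terms["A+C"] - terms["A"] - terms["C"]))
    pairDf <- c("A*B" = unname(dfs["A+B"] - dfs["A"] - dfs["B"]),
                "B*C" = unname(dfs["B+C"] - dfs["B"] - dfs["C"]),
                "A*C" = unname(dfs["A+C"] - dfs["A"] - dfs["C"]))
    terms <- c(terms, pair)
    dfs <- c(dfs, pairDf)
  }
  df <- as.integer(res$df)
  testable <- df >= 1L
  new("Chi2InteractionResult",
      snpTuple = snps, encoding = encoding,
      chi2Terms = terms, dfTerms = dfs,
      interactionStat = max(res$stat, 0), rawStat = res$stat,
      interactionDf = df, nUsed = prep$n,
      pRaw = if (testable) pchisq(max(res$stat, 0), df, lower.tail = FALSE)
             else NA_real_,
      testable = testable)
}

#' Logistic-regression interaction test for a pair or triple of SNPs
#'
#' Fits the product-term logistic model on the numeric genotype values of
#' the current encoding (initial: codes `{1,2,3}` as-is, or shifted to
#' `{0,1,2}` with `coding = "centered"`; binary: `{0,1}`), after pairwise
#' deletion. The interaction p-value is the two-sided Wald test of the
#' highest-order coefficient.
#'
#' @param x A [GenotypeExperiment-class].
#' @param snps 2 or 3 SNP ids (or indices).
#' @param coding `"as_is"` (default) or `"centered"` (initial encoding
#'   only).
#' @return A [LogisticInteractionFit-class].
#' @export
logisticInteraction <- function(x, snps, coding = c("as_is", "centered")) {
  stopifnot(is(x, "GenotypeExperiment"))
  snps <- .resolveSnps(x, snps)
  .checkBothClasses(phenotype(x))
  vals <- .genoValues(x)
  prep <- .prepLogisticTuple(vals, snps, genotypeEncoding(x), coding)
  if (prep$n == 0L) stop("no subject has complete genotypes for tuple ",
                         paste(snps, collapse = ", "))
  y <- as.integer(phenotype(x) == "case")[prep$subj + 1L]
  if (!prep$testable)
    return(new("LogisticInteractionFit", snpTuple = snps,
               encoding = genotypeEncoding(x), coefficients = numeric(0),
               se = numeric(0), interactionP = NA_real_,
               nUsed = prep$n, converged = FALSE, separation = FALSE,
               testable = FALSE))
  fit <- .logisticIrlsCpp(prep$X, y)
  k <- ncol(prep$X)
  usable <- fit$converged && !fit$singular && !fit$separation
  p <- if (usable) 2 * pnorm(-abs(fit$beta[k] / fit$se[k])) else NA_real_
  new("LogisticInteractionFit", snpTuple = snps,
      encoding = genotypeEncoding(x),
      coefficients = stats::setNames(fit$beta, colnames(prep$X)),
      se = stats::setNames(fit$se, colnames(prep$X)),
      interactionP = p, nUsed = prep$n,
      converged = fit$converged, separation = fit$separation,
      testable = !fit$singular)
}

#' Exhaustive interaction scan over all SNP pairs or triples
#'
#' Runs [chi2Interaction()] or [logisticInteraction()] for every unordered
#' SNP combination of the requested order, with per-tuple pairwise
#' deletion. An untestable tuple (interaction df < 1, constant predictor,
#' no complete subject, separation) is flagged and does not affect the
#' others.
#'
#' @param x A [GenotypeExperiment-class].
#' @param order 2 or 3.
#' @param method `"chi2"` or `"logistic"`.
#' @param coding Passed to [logisticInteraction()].
#' @return A data.frame with one row per combination, sorted by raw
#'   p-value (untestable tuples last) then tuple id: columns `snp1`,
#'   `snp2`, `snp3` (NA for pairs), `order`, `method`, `encoding`,
#'   `n_used`, `statistic`, `raw_stat`, `df`, `p_raw`, `p_adjusted` (NA
#'   until [permutationAdjust()]), `testable`. The scan's method and
#'   encoding are also attached as attributes.
#' @export
exhaustiveScan <- function(x, order = 2, method = c("chi2", "logistic"),
                           coding = "as_is") {
  stopifnot(is(x, "GenotypeExperiment"))
  method <- match.arg(method)
  if (!order %in% 2:3) stop("order must be 2 or 3")
  ids <- snpIds(x)
  if (length(ids) < order) stop("need at least ", order, " SNPs")
  .checkBothClasses(phenotype(x))
  vals <- .genoValues(x)
  y <- as.integer(phenotype(x) == "case")
  combos <- combn(ids, order, simplify = FALSE)
  rows <- lapply(combos, function(snps) {
    row <- list(snp1 = snps[1], snp2 = snps[2],
                snp3 = if (order == 3) snps[3] else NA_character_,
                order = order, method = method,
                encoding = genotypeEncoding(x),
                n_used = 0L, statistic = NA_real_, raw_stat = NA_real_,
                df = NA_integer_, p_raw = NA_real_,
                p_adjusted = NA_real_, testable = FALSE)
    if (method == "chi2") {
      prep <- .prepChi2Tuple(vals, snps)
      if (prep$n > 0L) {
        res <- .chi2DecomposeCpp(prep, y[prep$subj + 1L])
        df <- as.integer(res$df)
        row$n_used <- prep$n
        row$raw_stat <- res$stat
        row$df <- df
        if (df >= 1L) {
          row$statistic <- max(res$stat, 0)
          row$p_raw <- pchisq(row$statistic, df, lower.tail = FALSE)
          row$testable <- TRUE
        }
      }
    } else {
      prep <- .prepLogisticTuple(vals, snps, genotypeEncoding(x), coding)
      row$n_used <- prep$n
      if (prep$n > 0L && prep$testable) {
        fit <- .logisticIrlsCpp(prep$X, y[prep$subj + 1L])
        if (fit$converged && !fit$singular && !fit$separation) {
          k <- ncol(prep$X)
          z <- fit$beta[k] / fit$se[k]
          row$statistic <- z^2
          row$df <- 1L
          row$p_raw <- 2 * pnorm(-abs(z))
          row$testable <- TRUE
        }
      }
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  o <- order(out$p_raw, out$snp1, out$snp2, out$snp3,
             method = "radix", na.last = TRUE)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "method") <- method
  attr(out, "encoding") <- genotypeEncoding(x)
  attr(out, "coding") <- coding
  out
}

#' Permutation-based multiple-testing adjustment of a scan
#'
#' Case/control labels are permuted `nPermutations` times (genotypes
#' fixed; one seeded permutation stream shared by every tuple, so the
#' family-wise max-T adjustment is coherent) and the full scan statistic
#' set is recomputed per permutation on the common `-log10(p)` scale,
#' which makes tuples with different df comparable. The adjusted p-value
#' uses the add-one estimator:
#' `max_t` (default, family-wise): `(1 + #\{b : max_tuple stat_b >=
#' stat_obs(t)\}) / (B + 1)`; `per_test`: the same with each tuple
#' compared only to its own permutation distribution.
#'
#' @param x The [GenotypeExperiment-class] the scan was run on (same
#'   encoding).
#' @param observed A scan data.frame from [exhaustiveScan()] (orders may
#'   be mixed by `rbind`; method and encoding must be uniform).
#' @param nPermutations Number of label permutations (default 10000);
#'   0 returns `observed` unchanged.
#' @param adjust `"max_t"` or `"per_test"`.
#' @param seed Integer seed for the permutation stream.
#' @return `observed` with `p_adjusted` filled in (NA for untestable
#'   tuples, which are excluded from the family).
#' @export
permutationAdjust <- function(x, observed, nPermutations = 10000,
                              adjust = c("max_t", "per_test"), seed = 1L) {
  stopifnot(is(x, "GenotypeExperiment"), is.data.frame(observed))
  adjust <- match.arg(adjust)
  if (!.isCount(nPermutations)) stop("nPermutations must be a count")
  if (nPermutations == 0) return(observed)
  method <- unique(observed$method)
  encoding <- unique(observed$encoding)
  if (length(method) != 1 || length(encoding) != 1)
    stop("observed must come from a single method and encoding")
  if (encoding != genotypeEncoding(x))
    stop("encoding of x (", genotypeEncoding(x), ") does not match the ",
         "scan (", encoding, ")")
  coding <- attr(observed, "coding") %||% "as_is"
  vals <- .genoValues(x)
  y <- as.integer(phenotype(x) == "case")

  keep <- which(observed$testable)
  if (!length(keep)) return(observed)
  tuples <- lapply(keep, function(i) {
    snps <- stats::na.omit(unlist(observed[i, c("snp1", "snp2", "snp3")]))
    if (method == "chi2") .prepChi2Tuple(vals, snps)
    else .prepLogisticTuple(vals, snps, encoding, coding)
  })

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  permY <- vapply(seq_len(nPermutations), function(b) sample(y),
                  integer(length(y)))

  ## observed statistics recomputed through the identical kernel path so
  ## permuted and observed values are bit-comparable
  obsStat <- vapply(tuples, function(tp) {
    yy <- y[tp$subj + 1L]
    if (method == "chi2") .chi2DecomposeCpp(tp, yy)$neglog10_p
    else {
      fit <- .logisticIrlsCpp(tp$X, yy)
      if (fit$converged && !fit$singular && !fit$separation) {
        k <- ncol(tp$X)
        -(pnorm(-abs(fit$beta[k] / fit$se[k]), log.p = TRUE) + log(2)) /
          log(10)
      } else NA_real_
    }
  }, numeric(1))

  P <- if (method == "chi2") .permChi2Cpp(tuples, permY)
       else .permLogisticCpp(tuples, permY)

  B <- nPermutations
  padj <- rep(NA_real_, length(keep))
  if (adjust == "max_t") {
    M <- apply(P, 1, function(r) if (all(is.na(r))) -Inf else
      max(r, na.rm = TRUE))
    for (j in seq_along(keep))
      if (!is.na(obsStat[j]))
        padj[j] <- (1 + sum(M >= obsStat[j])) / (B + 1)
  } else {
    for (j in seq_along(keep))
      if (!is.na(obsStat[j]))
        padj[j] <- (1 + sum(P[, j] >= obsStat[j], na.rm = TRUE)) / (B + 1)
  }
  observed$p_adjusted[keep] <- padj
  observed
}

#' Total number of statistical evaluations of an exhaustive scan
#'
#' `(sum over orders of choose(nSnps, order)) * nPermutations` — the
#' arithmetic behind the cost of permutation-adjusted exhaustive scans
#' (e.g. 65 SNPs, orders \{2,3\}, 10,000 permutations gives 457.6 million).
#'
#' @param nSnps Number of SNPs.
#' @param orders Set of interaction orders (subset of `c(2, 3)`), possibly
#'   empty.
#' @param nPermutations Permutations per test.
#' @return The total count (double, to allow > 2^31).
#' @export
#' @examples
#' countTotalTests(65, c(2, 3), 10000)  # 457,600,000
countTotalTests <- function(nSnps, orders, nPermutations) {
  if (!length(orders)) return(0)
  stopifnot(all(orders >= 1), nSnps >= max(orders), nPermutations >= 0)
  sum(choose(nSnps, orders)) * nPermutations
}
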