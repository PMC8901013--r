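#' Specification for a synthetic case/control genotype cohort
#'
#' Bundles everything the generator needs: cohort sizes (defaults emulate
#' a cohort of 389 cases / 336 controls), per-SNP minor allele
#' frequencies, an optional logistic effect model (any subset of main and
#' interaction coefficients), optional latent genotype profiles defining
#' cluster structure, a missingness rate, and a seed.
#'
#' @param nCases,nControls Cohort sizes (defaults 389 and 336).
#' @param mafs Named (or unnamed) vector of per-SNP MAFs in `(0, 0.5]`;
#'   used when no profiles are given.
#' @param snpIds SNP ids; defaults to names of `mafs`/profile length.
#' @param effectModel Optional list: `intercept` plus `terms`, a list of
#'   `list(snps = <ids>, beta = <coef>)` entries evaluated on the chosen
#'   `coding` (`"centered"` = codes shifted to \{0,1,2\} (default),
#'   `"as_is"` = codes \{1,2,3\}, `"symmetric"` = codes shifted to
#'   \{-1,0,1\} around the heterozygote, which keeps single-SNP margins
#'   null under a pure product term at MAF 0.5, `"indicator"` = 1 when
#'   the genotype equals `modes[snp]`); omitted coefficients are 0.
#' @param coding Coding for the effect model (see above).
#' @param modes Named mode vector for `coding = "indicator"`.
#' @param profiles Optional list of latent profiles, each
#'   `list(modes = <codes in 1:3>, weight_cases =, weight_controls =,
#'   corruption =)`; per class the weights must sum to 1 and corruption
#'   (probability that a SNP deviates from the profile mode to a random
#'   other code; scalar or per-SNP vector) must be in `[0, 0.5)`.
#' @param missingRate Probability an entry is set missing, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(nCases = 389, nControls = 336, mafs = NULL,
                          snpIds = NULL, effectModel = NULL,
                          coding = c("centered", "as_is", "symmetric", "indicator"),
                          modes = NULL, profiles = NULL,
                          missingRate = 0, seed = 1L) {
  coding <- match.arg(coding)
  stopifnot(.isCount(nCases), .isCount(nControls), nCases > 0,
            nControls > 0, missingRate >= 0, missingRate < 1)
  if (is.null(mafs) && is.null(profiles))
    stop("either mafs or profiles must be given")
  if (!is.null(profiles)) {
    wc <- vapply(profiles, function(p) p$weight_cases %||% 1, numeric(1))
    wo <- vapply(profiles, function(p) p$weight_controls %||% 1, numeric(1))
    if (abs(sum(wc) - 1) > 1e-8 || abs(sum(wo) - 1) > 1e-8)
      stop("profile mixing weights must sum to 1 within each class")
    len <- unique(vapply(profiles, function(p) length(p$modes), integer(1)))
    if (length(len) != 1) stop("profile mode vectors differ in length")
    corr <- unlist(lapply(profiles, function(p) p$corruption %||% 0))
    if (any(corr < 0 | corr >= 0.5))
      stop("profile corruption must be in [0, 0.5)")
    if (is.null(snpIds)) snpIds <- paste0("SNP_", seq_len(len))
  }
  if (!is.null(mafs)) {
    if (any(mafs <= 0 | mafs > 0.5)) stop("mafs must lie in (0, 0.5]")
    if (is.null(snpIds))
      snpIds <- names(mafs) %||% paste0("SNP_", seq_along(mafs))
  }
  if (coding == "indicator" && !is.null(effectModel) && is.null(modes))
    stop("coding = 'indicator' requires modes")
  structure(list(n_cases = as.integer(nCases),
                 n_controls = as.integer(nControls),
                 mafs = mafs, snp_ids = snpIds, effect_model = effectModel,
                 coding = coding, modes = modes, profiles = profiles,
                 missing_rate = missingRate, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Per SNP, genotypes are drawn independently with the Hardy-Weinberg
#' probabilities `(q^2, 2pq, p^2)` for codes `(1 = aa, 2 = het, 3 = BB)`,
#' where `q` is the SNP's minor allele frequency.
#'
#' @param n Number of subjects.
#' @param mafs Per-SNP MAFs in `(0, 0.5]`.
#' @param seed Integer seed.
#' @return Integer matrix `n x length(mafs)` of codes in `{1,2,3}` with
#'   SNP column names.
#' @export
simulateGenotypes <- function(n, mafs, seed = 1L) {
  stopifnot(.isCount(n), n > 0)
  if (any(mafs <= 0 | mafs > 0.5)) stop("mafs must lie in (0, 0.5]")
  ids <- names(mafs) %||% paste0("SNP_", seq_along(mafs))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  g <- vapply(mafs, function(q) {
    probs <- c(q^2, 2 * q * (1 - q), (1 - q)^2)
    sample.int(3L, n, replace = TRUE, prob = probs)
  }, integer(n))
  if (n == 1L) g <- matrix(g, nrow = 1)
  colnames(g) <- ids
  g
}

.evalLinearPredictor <- function(g, effectModel, coding, modes) {
  eta <- rep(effectModel$intercept %||% 0, nrow(g))
  xval <- function(snp) {
    v <- g[, snp]
    switch(coding,
           as_is = as.numeric(v),
           centered = as.numeric(v) - 1,
           symmetric = as.numeric(v) - 2,
           indicator = as.numeric(v == modes[[snp]]))
  }
  for (term in effectModel$terms %||% list()) {
    if (!all(term$snps %in% colnames(g)))
      stop("effect model references unknown SNP(s): ",
           paste(setdiff(term$snps, colnames(g)), collapse = ", "))
    contrib <- Reduce(`*`, lapply(term$snps, xval))
    eta <- eta + term$beta * contrib
  }
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  eta
}

#' Simulate a case/control phenotype from a logistic effect model
#'
#' Per subject, the case probability is the logistic transform of
#' `intercept + sum_k beta_k * prod(x_snps_in_term_k)` evaluated on the
#' chosen coding, and the label is a Bernoulli draw.
#'
#' @param g Genotype matrix (subjects x SNPs, codes `{1,2,3}`, named
#'   columns) or a [GenotypeExperiment-class].
#' @param effectModel,coding,modes See [syntheticSpec()].
#' @param seed Integer seed.
#' @return Integer vector of labels (1 = case).
#' @export
simulatePhenotype <- function(g, effectModel,
                              coding = c("centered", "as_is", "symmetric", "indicator"),
                              modes = NULL, seed = 1L) {
  coding <- match.arg(coding)
  if (is(g, "GenotypeExperiment")) g <- genotypes(g)
  eta <- .evalLinearPredictor(g, effectModel, coding, modes)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  rbinom(nrow(g), 1L, plogis(eta))
}

#' Set genotypes missing at random
#'
#' Each entry is independently replaced by the missing code 0 with
#' probability `rate`.
#'
#' @param g Genotype matrix (subjects x SNPs).
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The matrix with missing codes injected.
#' @export
injectMissing <- function(g, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(g)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  hit <- matrix(runif(length(g)) < rate, nrow(g))
  g[hit] <- 0L
  g
}

## draw genotype rows from a profile mixture with given per-profile weights
.drawFromProfiles <- function(n, profiles, weights) {
  m <- length(profiles[[1]]$modes)
  which_p <- sample.int(length(profiles), n, replace = TRUE, prob = weights)
  g <- matrix(0L, n, m)
  for (pi in seq_along(profiles)) {
    rows <- which(which_p == pi)
    if (!length(rows)) next
    pr <- profiles[[pi]]
    block <- matrix(rep(as.integer(pr$modes), each = length(rows)),
                    nrow = length(rows))
    corrRate <- rep_len(pr$corruption %||% 0, m)   # scalar or per-SNP
    corrupt <- matrix(runif(length(rows) * m) <
                        rep(corrRate, each = length(rows)),
                      nrow = length(rows))
    if (any(corrupt)) {
      # replace by a uniformly random *different* code in {1,2,3}
      shift <- matrix(sample.int(2L, length(rows) * m, replace = TRUE),
                      nrow = length(rows))
      block[corrupt] <- ((block[corrupt] - 1L + shift[corrupt]) %% 3L) + 1L
    }
    g[rows, ] <- block
  }
  list(g = g, membership = which_p)
}

#' Simulate a clustered case/control population
#'
#' Two generation modes, chosen by the spec:
#'
#' * **Class-conditional profiles** (no `effectModel`): the requested
#'   numbers of cases and controls are drawn directly; each subject's
#'   genotype comes from its class's profile mixture, with each SNP equal
#'   to the profile mode with probability `1 - corruption` and a uniformly
#'   random different code otherwise.
#' * **Effect model** (`effectModel` given): genotypes are drawn from the
#'   pooled profile mixture and labels from the logistic model, with
#'   rejection sampling in batches until exactly `nCases`/`nControls`
#'   subjects of each class are collected (a case/control design has
#'   fixed margins). This is the mode that can plant an interaction
#'   *aligned with* a profile's modes via `coding = "indicator"`.
#'
#' Missingness is injected afterwards in either mode.
#'
#' @param spec A [syntheticSpec()] with `profiles` set.
#' @return A list: `genotypes` (a [GenotypeExperiment-class]),
#'   `membership` (generating profile index per subject), `spec`.
#' @export
simulateClusteredPopulation <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (is.null(spec$profiles)) stop("spec has no profiles")
  profiles <- spec$profiles
  nCa <- spec$n_cases; nCo <- spec$n_controls
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  wc <- vapply(profiles, function(p) p$weight_cases %||% 1, numeric(1))
  wo <- vapply(profiles, function(p) p$weight_controls %||% 1, numeric(1))

  if (is.null(spec$effect_model)) {
    ca <- .drawFromProfiles(nCa, profiles, wc)
    co <- .drawFromProfiles(nCo, profiles, wo)
    g <- rbind(ca$g, co$g)
    membership <- c(ca$membership, co$membership)
    labels <- rep(c(1L, 0L), c(nCa, nCo))
  } else {
    wpool <- (nCa * wc + nCo * wo) / (nCa + nCo)
    gCa <- gCo <- NULL
    memCa <- memCo <- integer(0)
    colnames_set <- spec$snp_ids
    guard <- 0L
    while (is.null(gCa) || nrow(gCa) < nCa || nrow(gCo) < nCo) {
      guard <- guard + 1L
      if (guard > 1000L)
        stop("rejection sampling failed to reach the requested class ",
             "counts; the effect model is too extreme")
      batch <- .drawFromProfiles(2L * (nCa + nCo), profiles, wpool)
      colnames(batch$g) <- colnames_set
      eta <- .evalLinearPredictor(batch$g, spec$effect_model, spec$coding,
                                  spec$modes)
      lab <- rbinom(nrow(batch$g), 1L, plogis(eta))
      gCa <- rbind(gCa, batch$g[lab == 1L, , drop = FALSE])
      gCo <- rbind(gCo, batch$g[lab == 0L, , drop = FALSE])
      memCa <- c(memCa, batch$membership[lab == 1L])
      memCo <- c(memCo, batch$membership[lab == 0L])
    }
    g <- rbind(gCa[seq_len(nCa), , drop = FALSE],
               gCo[seq_len(nCo), , drop = FALSE])
    membership <- c(memCa[seq_len(nCa)], memCo[seq_len(nCo)])
    labels <- rep(c(1L, 0L), c(nCa, nCo))
  }
  colnames(g) <- spec$snp_ids
  if (spec$missing_rate > 0)
    g <- injectMissing(g, spec$missing_rate,
                       seed = deriveSeed(spec$seed, "missingness"))
  ge <- GenotypeExperiment(g, labels, snpIds = spec$snp_ids,
                           phenotypeCoding = "01")
  list(genotypes = ge, membership = membership, spec = spec)
}

#' Simulate an unstructured case/control cohort
#'
#' Hardy-Weinberg genotypes ([simulateGenotypes()]) plus a phenotype from
#' the spec's effect model (or a coin flip when none), rejection-sampled
#' in batches to exactly `nCases`/`nControls`, with missingness injected
#' afterwards.
#'
#' @param spec A [syntheticSpec()] with `mafs` set.
#' @return A [GenotypeExperiment-class].
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (is.null(spec$mafs)) stop("spec has no mafs")
  nCa <- spec$n_cases; nCo <- spec$n_controls
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  gCa <- gCo <- NULL
  guard <- 0L
  while (is.null(gCa) || nrow(gCa) < nCa || nrow(gCo) < nCo) {
    guard <- guard + 1L
    if (guard > 1000L)
      stop("rejection sampling failed; the effect model is too extreme")
    n <- 2L * (nCa + nCo)
    g <- vapply(spec$mafs, function(q)
      sample.int(3L, n, replace = TRUE,
                 prob = c(q^2, 2 * q * (1 - q), (1 - q)^2)), integer(n))
    colnames(g) <- spec$snp_ids
    eta <- if (is.null(spec$effect_model)) rep(0, n)
           else .evalLinearPredictor(g, spec$effect_model, spec$coding,
                                     spec$modes)
    lab <- rbinom(n, 1L, plogis(eta))
    gCa <- rbind(gCa, g[lab == 1L, , drop = FALSE])
    gCo <- rbind(gCo, g[lab == 0L, , drop = FALSE])
  }
  g <- rbind(gCa[seq_len(nCa), , drop = FALSE],
             gCo[seq_len(nCo), , drop = FALSE])
  if (spec$missing_rate > 0)
    g <- injectMissing(g, spec$missing_rate,
                       seed = deriveSeed(spec$seed, "missingness"))
  GenotypeExperiment(g, rep(c(1L, 0L), c(nCa, nCo)),
                     snpIds = spec$snp_ids, phenotypeCoding = "01")
}

#' Study conditions for the clustered-interaction validation cohort
#'
#' The packaged synthetic analogue of a small case/control epistasis
#' cohort: 389 cases / 336 controls typed at 7 SNPs, two latent genotype
#' profiles (all-homozygous-minor vs all-homozygous-major modes, equal
#' mixing), and a protective two-locus interaction planted on the
#' indicator of carrying the first profile's mode at SNP_1 and SNP_2
#' (`beta = -2` on the product, intercept 0.5, no main effects). The five
#' remaining SNPs carry the cluster signal (corruption 0.15); the two
#' interacting SNPs are only loosely coupled to the profiles (corruption
#' 0.45) so the interaction is not a mere proxy of the latent class.
#' Genotypes are 1% missing at random.
#'
#' Subjects carrying the first profile's modes at both loci are depleted
#' among cases, so the first-profile clusters end up controls-enriched and
#' the cluster-mode binary encoding recovers exactly the planted risk
#' indicator -- the configuration under which the encoding's
#' degrees-of-freedom advantage should show.
#'
#' @param seed Integer seed.
#' @param nCases,nControls Cohort sizes.
#' @param beta Interaction coefficient (default -2).
#' @param missingRate Missingness (default 0.01).
#' @return A [syntheticSpec()].
#' @export
clusteredInteractionSpec <- function(seed = 1L, nCases = 389,
                                     nControls = 336, beta = -2,
                                     missingRate = 0.01) {
  ids <- paste0("SNP_", 1:7)
  p1 <- rep(1L, 7); p2 <- rep(3L, 7)
  corr <- c(0.45, 0.45, rep(0.15, 5))
  syntheticSpec(
    nCases = nCases, nControls = nControls, snpIds = ids,
    profiles = list(
      list(modes = p1, weight_cases = 0.5, weight_controls = 0.5,
           corruption = corr),
      list(modes = p2, weight_cases = 0.5, weight_controls = 0.5,
           corruption = corr)),
    effectModel = list(intercept = 0.5,
                       terms = list(list(snps = c("SNP_1", "SNP_2"),
                                         beta = beta))),
    coding = "indicator", modes = stats::setNames(p1, ids),
    missingRate = missingRate, seed = seed)
}
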