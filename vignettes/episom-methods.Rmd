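---
title: "EpiSOM: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EpiSOM: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EpiSOM)
```

# The problem

Statistical epistasis — gene–gene interaction measured as deviation from
additivity in a model linking multi-locus genotypes to a phenotype — is
hard to detect in case/control SNP studies for two reasons that compound
each other. Exhaustively testing all $\binom{k}{2}$ pairs and
$\binom{k}{3}$ triples of $k$ SNPs multiplies the number of tests, and
multi-locus genotype tables spread the association over many degrees of
freedom, costing power exactly where the multiple-testing burden demands
more of it. `countTotalTests(65, c(2, 3), 10000)` — a modest 65-SNP panel
with 10,000 permutations — is already 457.6 million statistic
evaluations.

EpiSOM implements a four-step framework that attacks both ends:

1. **Quality control** (`applyQC`) removes SNPs with poor data quality.
2. **Feature selection** (`rfImportance`, `selectTopK`) keeps the SNPs a
   Random Forest finds most class-informative, shrinking $k$.
3. **Clustering** (`trainSOM`, `assignClusters`) groups subjects by
   genotype similarity with a self-organizing map for nominal data, and
   checks by a Pearson $\chi^2$ test whether cluster membership separates
   cases from controls.
4. **Binary encoding + testing** (`binarizeMatrix`, `exhaustiveScan`,
   `permutationAdjust`) re-expresses each SNP as "carries the reference
   cluster's most frequent genotype (1) or not (0)" and runs exhaustive
   2-SNP and 3-SNP interaction tests on both the original 3-level coding
   and the binary recoding, with permutation-based multiple-testing
   adjustment.

Genotypes are coded categorically throughout: 1 = homozygous minor (aa),
2 = heterozygous (aB/Ba), 3 = homozygous major (BB), 0 = missing. The
codes are *nominal* — no dosage ordering is assumed in QC, clustering or
the $\chi^2$ tests.

# The interaction statistics

## Chi-square decomposition

For SNPs $A$ and $B$, let $\chi^2_{A+B}$ be the Pearson statistic of the
joint genotype-combination variable (one row per observed combination)
against case/control status — the *omnibus* effect — and $\chi^2_A$,
$\chi^2_B$ the single-SNP statistics on the same subjects. The
interaction statistic and its degrees of freedom are the differences

$$\chi^2_{A*B} = \chi^2_{A+B} - \chi^2_A - \chi^2_B,\qquad
  DF_{A*B} = DF_{A+B} - DF_A - DF_B.$$

For triples the omnibus term is decomposed further, subtracting the three
pairwise interaction terms (each itself a difference on the same subject
subset) and the three main effects:

$$\chi^2_{A*B*C} = \chi^2_{A+B+C} - \chi^2_{A*B} - \chi^2_{B*C} -
  \chi^2_{A*C} - \chi^2_A - \chi^2_B - \chi^2_C,$$

with $DF_{A*B*C}$ composed identically. On fully observed 3-level SNPs
this gives $8 - 2 - 2 = 4$ df for a pair and
$26 - 3\cdot4 - 3\cdot2 = 8$ df for a triple; on binary-encoded SNPs both
collapse to **1 df** ($3-1-1$ and $7 - 6\cdot1$) — this df reduction is
the power argument for the encoding.

```{r df}
interactionDf(chi2Interaction(
  GenotypeExperiment(
    as.matrix(expand.grid(S1 = 1:3, S2 = 1:3, S3 = 1:3))[rep(1:27, 4), ],
    rep_len(0:1, 108)),
  c("S1", "S2", "S3")))
```

Numerical details, decided once:

* **Realized dimensions.** Empty rows (unobserved combinations) are
  dropped from every component table and df terms use the realized
  dimensions, so the df identity stays self-consistent on sparse data;
  the composed df can then fall below the theoretical value, and a tuple
  with composed df $< 1$ is flagged untestable rather than forced.
* **Negative differences.** The decomposition is a difference of
  statistics and can go negative (e.g. two nearly collinear SNPs sharing
  one main effect). The $\chi^2$ reference distribution needs a
  non-negative statistic, so the value is truncated at 0 for the p-value
  and the signed value is kept in `rawStat`.
* **Pairwise deletion.** Per tuple, only subjects missing a genotype in
  that tuple's SNPs are removed; other tuples keep them.

## Logistic regression

`logisticInteraction` fits the saturated product-term model
$\operatorname{logit} p = \beta + \beta_A x_A + \beta_B x_B +
\beta_{AB} x_A x_B$ (triples add all pairwise products and the triple
product) by IRLS, and tests the highest-order coefficient with a
two-sided Wald test. Genotypes enter numerically as coded
(initial: $\{1,2,3\}$ as-is, optionally shifted to $\{0,1,2\}$; binary:
$\{0,1\}$). A constant predictor after deletion, a singular information
matrix, non-convergence, or separation (any $|\hat\eta| > 30$) is
reported as an untestable/unusable fit with no fabricated p-value. The
Wald choice (rather than a likelihood-ratio test) keeps one fit per
tuple, which matters inside the permutation loop; the fits agree with
`stats::glm` to $10^{-6}$ in the test suite.

## Permutation adjustment

`permutationAdjust` permutes the case/control labels (genotypes fixed),
recomputes the full scan per permutation, and uses the add-one estimator
$(1 + r)/(B + 1)$. The default is **max-T** family-wise adjustment: each
observed statistic is compared with the permutation distribution of the
per-permutation *maximum* over tuples, taken on the common
$-\log_{10} p$ scale so tuples with different df are comparable. A
single seeded permutation stream is shared by all tuples — required for
the max-T family to be coherent. `per_test` mode compares each tuple
only with its own permutation distribution. Untestable tuples are
excluded from the family and keep `NA`. Observed statistics are
recomputed through the identical compiled kernel used for the permuted
ones, so ties compare exactly.

# The categorical SOM

Subjects are clustered on a small rectangular grid of units. Each unit
holds per-SNP category-frequency tables over the codes $\{0,1,2,3\}$
(missing is an ordinary fourth category here, matching the nominal
treatment), and its prototype is the **mode vector** — the most frequent
code per SNP, ties to the smallest code. Distance between a subject and
a unit is the **Hamming distance** between code vectors.

Training is frequency accumulation: per epoch, every subject's
best-matching unit (BMU) is found against the current modes; the
subject's codes are added to the BMU's tables with weight 1 and to every
unit within the current neighbourhood radius (Chebyshev grid distance)
with weight $0.5^d$; modes are recomputed at epoch end. The radius
starts at half the map's longer edge and decays linearly to 0 over the
epochs (default 1000). Counts are never reset, so prototypes stabilize
as evidence accumulates and no learning-rate schedule is needed.

Three design points here were forced by failure analysis rather than
taste:

* **Decaying neighbourhood weight.** With a flat bubble weight, every
  unit inside the radius accumulates *identical* frequencies whenever
  the radius spans the grid (epoch 1 always does), the argmax modes
  coincide, and the map can never differentiate — the two-profile
  recovery fixture sits at chance. The $0.5^d$ weight preserves the
  topological smoothing while keeping per-unit evidence distinct.
* **Farthest-point initialization.** The first prototype is a seeded
  draw from the subject rows; each further unit takes the row maximizing
  its minimum Hamming distance to those already chosen. Distinct latent
  profiles are then represented from epoch 1.
* **Hash tie-breaks in training.** BMU ties are broken by a
  deterministic hash of the subject's genotype vector. This is
  reproducible given the seed, invariant to subject order (the hash
  ignores row position; initialization also works on a hash-canonical
  ordering), and — unlike "smallest unit index" — does not funnel all
  tied subjects into one unit, which would freeze a symmetric map.
  Inference-time assignment (`assignClusters`) keeps the conventional
  smallest-index tie-break.

**Map-size selection** (`selectMapSize`) evaluates candidate grids
(default $1\times2$ … $4\times4$) by stratified $k$-fold cross-validation
(default $k=2$), repeated (default 10) with fresh seeds: train on the
training fold, assign both folds, and test the clusters-by-class
contingency table with Pearson $\chi^2$. Selection uses the **median
held-out p-value** — the median is robust to degenerate folds (a
single-occupied-cluster evaluation counts as $p=1$), and the held-out
side avoids rewarding overfit maps. The analysis proceeds past the
clustering step only when the winning p-value passes the significance
gate ($\le 0.05$ by default).

**Reference cluster and encoding.** Clusters are labelled by majority
class (a tie takes the overall minority class and is flagged). The
reference cluster for the encoding is, by default, the most deviant
cluster of the rarer majority label — e.g. the single controls-majority
cluster of a map otherwise dominated by cases clusters — scoring
candidates by $|\text{case fraction} - \text{overall case fraction}|
\times \text{size}$; an explicit override always wins. Binarization
maps, per SNP, the reference cluster's *member-recomputed* mode
(missing excluded — a "most frequent genotype" of missing is not
meaningful for encoding) to 1 and every other observed genotype to 0;
missing stays missing.

# Feature selection

`rfImportance` grows a 50-tree classification Random Forest (the
`randomForest` package) on the genotypes as nominal factors — the
missing code stays a level, consistent with the clustering step — and
ranks SNPs by Mean Decrease in Gini, reporting the out-of-bag error
alongside. Columns are put in canonical id order before fitting so the
ranking cannot depend on input column order; importance ties break
lexicographically. The number of selected SNPs `k` is deliberately a
user decision made by inspecting the importance profile; `elbowK` (the
largest relative drop) is offered as a labelled heuristic only, because
no principled universal rule exists at these panel sizes.

# The synthetic cohort generator

No genotype data ships with the package; every test runs on synthetic
cohorts built by the `synthetic` module, which emulates the structure
the framework assumes at the scale of a small association study
(defaults: 389 cases / 336 controls):

* `simulateGenotypes` — independent SNPs in Hardy–Weinberg proportions
  $(q^2, 2pq, p^2)$ at configurable MAFs (the null that `hweTest`
  checks).
* `simulatePhenotype` — logistic case probabilities from an effect model
  with arbitrary main/product terms on a chosen coding; the
  `"symmetric"` coding ($\{-1,0,1\}$) keeps single-SNP margins exactly
  null under a pure product term at MAF 0.5, which is how the suite
  verifies the generator plants interaction rather than marginal signal.
* `simulateClusteredPopulation` — latent genotype profiles (mode vector,
  per-class mixing weight, scalar or per-SNP corruption probability).
  Without an effect model, genotypes are drawn class-conditionally.
  With one, genotypes come from the pooled mixture, labels from the
  logistic model, and batches are rejection-sampled to the exact
  case/control margins of a case/control design.

`clusteredInteractionSpec` freezes the package's standard validation
cohort: 7 SNPs, two latent profiles (modes all-aa vs all-BB, equal
mixing), and a protective interaction $\beta = -2$ on the indicator of
carrying the *first* profile's mode at SNP_1 and SNP_2 (intercept 0.5,
no main terms). The five profile-defining SNPs have corruption 0.15 —
enough noise to be realistic, little enough that a $2\times2$ map
recovers the structure; the two interacting SNPs have corruption 0.45,
so the planted interaction is carried by the loci themselves and is not
a mere proxy of the latent class (strong profile coupling would also
make the product term nearly collinear with its mains and blind the
Wald test). Carriers of the protective pattern are depleted among
cases, so first-profile clusters come out controls-enriched and the
cluster-mode binary encoding reconstructs exactly the planted risk
indicator — the configuration in which the df advantage of the encoding
should, and in the test suite does, let both methods flag at least as
many interactions as the 3-level coding.

What the generator does **not** emulate: linkage-disequilibrium
haplotype structure, population stratification, genotyping batch
effects, covariates. Passing tests therefore show the machinery behaves
as designed under its own assumptions, not that any particular real
cohort satisfies them.

# Problem sizes and determinism

The test suite exercises the full pipeline at the cohort scale the
package targets (725 subjects, 7 SNPs) with shortened stochastic loops
chosen as sensible validation sizes: SOM fits at 100 epochs (the
two-profile fixtures converge well before that; the 1000-epoch default
is kept for real analyses), 500 label permutations for the max-T
comparisons, 50 replicates for the encoding-comparison study, and 500
replicates for the type-I calibration at $n = 2000$. Every stochastic
component takes an explicit integer seed; a single pipeline seed fans
out to stage seeds via `deriveSeed(seed, stage)` (a small string hash,
kept below $2^{31}$), and re-running a pipeline configuration reproduces
every output byte-for-byte.

# Known limitations

* The SOM update rule is this package's own frequency-accumulation
  formulation, specified completely above; other categorical-SOM
  variants (and k-modes) would be drop-in alternatives at the module
  boundary but are not implemented.
* Orders above 3 are not exposed: the decomposition generalizes, but
  contingency tables over $\ge 4$ SNPs are too sparse at these cohort
  sizes for the realized-df identity to be informative.
* No covariate adjustment — the interaction models contain genotype
  terms only.
* The $\chi^2$ method inherits the usual small-expected-count caveats;
  with pairwise deletion and 3-level SNPs, sparse cells reduce the
  realized df rather than invalidating the statistic, but very small
  clusters of subjects can still make individual tuples untestable.
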