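---
title: "Methods: factorial multiple-stressor inference in facstress"
author: "facstress maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factorial multiple-stressor inference in facstress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`facstress` analyses crossed two-level multi-stressor RNA-seq
experiments: a 2×2×2 factorial of salinity, fine sediment and flow
velocity with eight replicate mesocosm libraries per cell (64 samples)
is the reference design, but any 1–4 two-level factors are supported.
This vignette is the package's own account of the statistical choices:
the model, the defaults and why, what the synthetic-data generator does
and does not emulate, and the known limitations.

```{r setup, eval = FALSE}
library(facstress)
res <- run_pipeline(run_config(n_genes = 1000), out_dir = "demo", seed = 42)
```

## Input model and preprocessing

The pipeline starts from *estimated* transcript counts (non-negative
reals, as produced by lightweight abundance estimators), a
transcript→gene map and per-transcript effective lengths.
`summarise_to_gene()` sums member-transcript counts (column totals are
conserved exactly) and records a per-gene, per-sample average effective
length weighted by transcript abundance — weight `count/length`, the
natural estimate of molecule counts — falling back to the unweighted
mean when a gene is silent in a sample.  Gene effective lengths are
carried for round-trip checks of the generator but do **not** enter the
GLM: with a single species and within-gene comparisons across samples,
gene-length terms cancel to first order, so normalisation uses
per-sample size factors only.  This is a documented limitation: designs
where effective length shifts systematically across conditions
(differential isoform usage correlated with treatment) would need an
offset matrix, which `facstress` does not provide.

Size factors are median-of-ratios: the reference profile is the per-gene
geometric mean over samples, restricted to genes positive everywhere;
each sample's factor is the median ratio to the reference, and the
vector is rescaled to geometric mean 1 so that the intercept keeps the
scale of the data.  Filtering retains genes with at least
`min_count = 10` *normalised* counts in at least `min_samples = 8`
samples — with eight replicates per cell this keeps genes expressed in
as little as one full treatment cell.  Filtering applies normalised
(not raw) counts, and is applied after gene summarisation.

The variance-stabilising transform used for surrogate estimation and
clustering is the shifted log `log2(count/s_j + 1)`: monotone,
dispersion-free and invariant to joint rescaling of counts and size
factors.  It does not equalise variance as exactly as a
dispersion-aware transform at low counts; it is used only where ranks
and profiles matter (correction, z-scores, clustering), never for
inference.

## Surrogate variables

Unwanted structure (library batch, lane, handling time) is estimated
from what the design does not explain.  Expression is residualised on
the full factorial model; the right singular vectors of the residual
matrix are candidate surrogates, and their number is chosen by a
permutation ("parallel analysis") test: each gene's residuals are
permuted independently, the permuted matrix is **re-residualised on the
design**, and a component is retained while its variance share exceeds
the 95th percentile (`alpha = 0.05`) of its permuted shares, counting
leading components only (`n_perm = 100` by default).  The
re-residualisation step matters: the observed residuals satisfy a rank
constraint (they live in the n − p dimensional complement of the design
space), and a null spectrum computed without imposing the same
constraint is stochastically too flat, declaring every component
significant even on i.i.d. noise.

Because residuals are orthogonal to the intercept, surrogates have zero
mean; SVD makes them mutually orthogonal.  Downstream, the GLM design is
exactly `[factorial design | surrogates]`.  For visualisation and
clustering, `freeze_correct()` fits each gene by least squares on the
combined matrix and subtracts only the surrogate contribution, so
design-attributable signal is untouched (exactly so in balanced designs,
where the crossed batch is orthogonal to the treatment columns).

This residual-SVD-plus-permutation construction is a deliberate
simplification of iteratively reweighted surrogate-variable algorithms:
it is fully specified, deterministic given the seed, and testable, at
the cost of not down-weighting genes by their design association.  On
the generator's conditions (30% of genes batch-loaded at ±1 log2 unit)
it recovers the batch with |r| > 0.99 and removes > 99% of the
batch-mean separation.

## Negative-binomial inference

Each gene is fit by its own NB GLM with log link and offset
`log(s_j)`, maximised by Fisher-scoring IRLS (weights
`mu/(1 + alpha*mu)`), at most 100 iterations, declared converged when
the largest natural-log coefficient change falls below 1e-8.
Coefficients and standard errors are reported in log2 units; the
linear predictor is clamped to ±30 natural-log units to survive
quasi-separation, and a design cell of all-zero counts yields a
coefficient capped at ±10 log2 units with the gene flagged (never
silently dropped).

Dispersion is estimated per gene by method of moments on the Pearson
residuals of a Poisson fit, `(sum(r^2) − df_resid)/sum(mu)`, floored at
1e-8.  There is no empirical-Bayes moderation across genes — with eight
replicates per cell the per-gene estimate is usable on its own, and the
absence of a fitted mean–dispersion trend keeps the estimator free of
cross-gene assumptions.  An optional Cox–Reid refinement
(`estimate_dispersion(..., refine = TRUE)`) maximises the adjusted
profile likelihood in log-dispersion; it is less noisy but slightly
conservative downstream, so the moment estimate is the default.

**Reference distribution.**  Because each standard error contains an
estimated dispersion, the per-gene Wald statistic is not standard
normal in finite samples: its null tails match a t distribution with
roughly the residual degrees of freedom.  At the 64-sample design the
mismatch is visible — with a normal reference about 5.5% of null
p-values fall below 0.05, exactly P(|t56| > 1.96) — and propagates into
the FDR.  `fit_factorial_nb()` therefore uses a t reference with
`df = n − p` (a documented argument; `df = Inf` recovers the
asymptotic normal).  The exported `wald_test()` helper keeps the plain
normal convention for externally supplied estimates.  In the package's
seeded benchmarks this choice gives per-term null p-values that pass a
Kolmogorov–Smirnov uniformity test at the 0.01 level on 2000 genes and
a pooled empirical FDR of about 0.12 at nominal 0.1 (20 replicates of
the 1000-gene standard simulation), with sensitivity about 0.78 for
true effects at mean normalised count ≥ 50.

Multiple testing is Benjamini–Hochberg within each model term across
genes (seven term-wise families), matching per-treatment DE lists; the
significance threshold defaults to adjusted p < 0.1.  No cross-term
correction is applied.

## Adaptive LFC shrinkage

Observed log2 fold changes are shrunk with a zero-centred
scale-mixture-of-normals prior: a point mass at 0 plus normal
components on a geometric grid from `min(SE)/10` to `2*max|beta|` with
ratio √2.  Mixture weights are fit by EM on the marginal likelihood
`beta_hat ~ N(0, tau_k^2 + SE^2)` (convergence at log-likelihood gain
< 1e-8 or 1000 iterations); the reported value is the posterior-mean
LFC.  The prior is fit separately per model term, since main effects
and interactions have different effect-size distributions.  A
zero-centred unimodal prior guarantees the posterior mean never exceeds
the estimate in magnitude.  Shrunken LFCs feed the interaction calls,
the treatment dendrogram and the exported results table.

## Interaction classification

Under treatment coding, the *expected* combined LFC of a combination is
the sum of all its lower-order terms: `beta_A + beta_B` for a pair, and
all three mains plus all three pairwise terms for the three-way
combination (the all-lower-order convention; the observed combined
effect is then expected + interaction, an identity of the coding).
Only genes whose interaction term is significant are classified:

| expected | interaction | class |
|---|---|---|
| > 0 | > 0 | S+ |
| > 0 | < 0 | A+ |
| < 0 | < 0 | S− |
| < 0 | > 0 | A− |

An expectation within `eps = 1e-6` log2 units of zero is classified by
the interaction sign alone as synergistic (any deviation from a null
expectation amplifies it); this edge convention is explicit in
`classify_interaction()` and exercised in tests.  The count table
produced by `tabulate_interactions()` lists the pairwise combinations
alphabetically and the three-way combination last, with per-combination
totals.

Exclusive intersections (`exclusive_intersections()`) assign every
differentially expressed gene to the exact subset of treatment sets
containing it — the partition an UpSet plot displays — and the
treatment dendrogram clusters the seven treatment columns of the
shrunken-LFC matrix by Euclidean distance with average linkage,
zeroing non-significant entries first so the distance matrix stays
complete.

## Profile clustering

Interaction genes are clustered on z-scored, surrogate-corrected VST
values: per gene, centre and scale across samples (constant genes map
to zero rows and are flagged), then average over the eight design cells
— the resolution at which condition profiles are interpretable —
cluster agglomeratively with correlation distance (1 − Pearson r,
average linkage), and cut the tree at the k in [2, `k_max = 8`]
maximising the mean silhouette width.  Clusters smaller than
`min_size = 10` are dissolved and their genes reported as unassigned in
a single pass (no re-clustering).  Gene order is normalised internally,
so memberships do not depend on input order; if all profiles share one
shape the procedure short-circuits to a single cluster.  Silhouette
model selection plus agglomeration was chosen over consensus/divisive
alternatives for determinism and testability.

## Enrichment

Annotations are propagated to ancestors under the true-path rule with
set semantics (a diamond counts a gene once).  Each term is tested by
the one-sided hypergeometric tail P(X ≥ k) with the universe defined as
*all genes tested for differential expression*, and up- and
down-regulated study sets are tested separately.  The elim pass
processes terms leaves-first (reverse topological order); when a term's
current p-value falls below `alpha_elim = 0.01` its study hits are
removed from all ancestors before those are tested, so a parent
significant only through a significant child loses that support.  Both
raw and elim-adjusted p-values are reported, with no multiple-testing
correction across terms (the convention of elim-style procedures —
the decorrelation itself is the correction being offered).  The elim
variant was implemented rather than a hybrid weighting scheme because
it has published pseudocode, is deterministic, and its behaviour on
toy DAGs can be verified by hand.

## The synthetic-data generator

`sample_truth()` + `simulate_counts()` emulate the study conditions the
pipeline targets: 64 libraries in a 2×2×2 design; per-gene NB counts
with `mu = s_j * 2^(beta0 + x'beta + gamma*batch)`; a latent binary
batch *crossed* with the design (half of each cell's replicates), so
surrogate recovery is identifiable; 1–4 isoforms per gene with
log-uniform lengths in [300, 5000] bases and Dirichlet(1) usage
weights, with gene counts partitioned to isoforms as reals (mimicking
estimated counts — the GLM accepts non-integers throughout).

Where the study conditions do not pin a parameter, the defaults are
one-time choices of realistic RNA-seq magnitudes: log2 effect sizes
±N(1, 0.25²); dispersions log-normal with median 0.1 (sdlog 0.5);
baseline means log-uniform in [5, 5000] so the expression range spans
the filter boundary; 10% of genes with main effects only, 5% with an
injected interaction of uniformly mixed class and combination; 30% of
genes batch-loaded at strength 1.  Injected classes are consistent by
construction: an A+ gene is drawn with positive mains on its
combination and a negative interaction, and re-deriving the class from
the true coefficients returns the stored label exactly.

What the generator does **not** emulate: biological pooling of
specimens within a mesocosm (absorbed into the dispersion), read-level
noise and mapping ambiguity (counts are drawn at the transcript level
directly), assembly artefacts and annotation error, and
mean–dispersion trends.  Passing the benchmark suite therefore
demonstrates statistical correctness of the pipeline under the NB
model, not robustness to upstream artefacts of real sequencing data.

## Problem sizes and numerical conventions

The seeded benchmarks use 2000-gene global-null replicates and
1000-gene standard replicates (20 each), three 2000-gene runs for
interaction-class recovery, an 800-gene run for surrogate recovery and
45 planted genes for clustering recovery — sizes at which every
quantity of interest is stable while a full run stays in the
minutes range on one core.  Numerical conventions collected in one
place: IRLS convergence 1e-8 on natural-log coefficients, max 100
iterations; dispersion floor 1e-8; linear-predictor clamp ±30 (natural
log); LFC clamp ±10 (log2) on separation; EM tolerance 1e-8, max 1000
iterations; classification eps 1e-6 log2 units; correlation-distance
tie-break by gene id; silhouette grid k = 2..8; permutation test
alpha 0.05, 100 permutations.

## Known limitations

* No gene-length offset matrix (see preprocessing); no TPM/FPKM.
* Per-gene dispersion without cross-gene moderation needs several
  replicates per cell; the design here provides eight.
* The surrogate test assumes latent structure is visible in the
  residual spectrum; batch effects aligned with the design are
  unidentifiable by construction.
* Likelihood-ratio tests, outlier replacement (Cook's-distance style)
  and independent-filtering optimisation are out of scope.
* The shrinkage prior is zero-centred and unimodal per term; strongly
  asymmetric effect distributions would call for a component mean grid.
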