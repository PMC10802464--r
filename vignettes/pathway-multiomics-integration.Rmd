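---
title: "Pathway-based multi-omics integration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-based multi-omics integration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathpls)
```

## The problem

Multi-omics studies measure hundreds to tens of thousands of molecules —
metabolites, proteins, transcripts — on the same individuals, and the
question is usually not "which molecules differ?" but "which *biological
processes* differ, and can they predict the outcome?". pathpls answers this
by moving the modelling from the molecular space to the pathway space:
each omics block is condensed into per-sample *pathway activity scores*,
and a supervised latent-variable model is fitted to those scores. Pathway
scores put heterogeneous omics on a common scale, reduce dimension, and —
because a pathway aggregates many correlated, individually weak signals —
can detect coordinated shifts that molecule-level tests miss.

## Single-sample pathway scores (ssPA)

For pathway $p_i$ with $L_i$ molecules observed in the data, let
$Z_i$ be the $N \times L_i$ sub-matrix of the unit-variance-scaled
abundances of its members.

* **SVD / PLAGE method** (`sspa_svd`). The activity score vector is the
  projection on the first right singular vector,
  $a_i = Z_i v_1$, i.e. the first principal-component scores of the
  pathway sub-matrix. Because $Z_i$ is column-centred, $a_i$ has zero
  mean and $\lVert a_i \rVert$ equals the first singular value.
  $v_1$ doubles as molecule-level loadings: the contribution of each
  member to the score (`molecule_loadings`), with bootstrap stability
  available via `bootstrap_molecule_loadings`.
* **RBF kernel-PCA method** (`sspa_kpca`). An RBF kernel
  $K_{uv} = \exp(-\gamma \lVert z_u - z_v \rVert^2)$ over samples is
  double-centred and eigendecomposed; scores are the leading eigenvector
  scaled by $\sqrt{\lambda_1}$. This captures non-linear pathway
  coordination at the cost of molecule-level interpretability.

Both methods store their fitted state so held-out samples are *projected*
onto the training decomposition (`predict`), never refitted — together
with train-fitted scaling (`uv_scale` / `apply_uv_scale`) this makes
cross-validation leak-free.

**Sign convention.** The sign of a principal direction is arbitrary; we
orient every $v_1$/eigenvector so that its largest-magnitude entry is
positive (ties broken at the lowest column index). Scores then become
deterministic and exactly invariant to pathway member ordering.

**Kernel bandwidth.** `gamma = "auto"` uses $1/L_i$ per pathway, the
scale-free default for standardised inputs.

**Score scaling.** Whether kernel-PCA scores are multiplied by
$\sqrt{\lambda_1}$ differs between implementations; the two conventions
differ by a positive per-pathway constant, which is irrelevant downstream
because model input blocks are unit-variance scaled again. We scale by
$\sqrt{\lambda_1}$ so that training self-projection and new-sample
projection share one formula.

## The Multi-View model: multi-block PLS

With $k \ge 2$ pathway-score blocks $A_1,\dots,A_k$ (one per omics view)
and an outcome $y$, `fit_multiview` fits a NIPALS multi-block PLS model.
Per latent variable (LV):

1. each block receives a unit-norm weight vector $w_k$ and block scores
   $t_k = A_k w_k$;
2. block scores are combined through unit-norm *superweights* $a$ into the
   superscore $t_s = [t_1 \cdots t_k]\, a$;
3. $t_s$ predicts the response scores, and **all** blocks and $Y$ are
   deflated with $t_s$ (the Westerhuis–Coenegracht variant), which renders
   successive superscores mutually orthogonal.

Binary outcomes are encoded as a single centred 0/1 column and classified
at the encoding midpoint; continuous outcomes pass through unchanged. The
squared superweights $a_k^2$ sum to one across blocks per LV and are
reported as *block importances*: the contribution of each omics view to
the explained outcome variance (`block_importance`, with bootstrap means
and standard deviations via `bootstrap_block_importance`).

For a single predictor matrix, `fit_pls` implements classical NIPALS PLS
(deflation by X-loadings), which is also the engine behind the PLS-DA
predictor of the Single-View framework. The two deflation schemes are kept
deliberately distinct: the single-block model follows the textbook
recursion $X_{r+1} = X_r - t_r v_r^T$, while the multi-block model uses
superscore deflation, whose orthogonality property the block importances
rely on.

## Pathway importance: VIP and MB-VIP

Variable importance in projection combines the squared model weights with
each LV's share of the explained sum of squares of $y$ ($SSY_r$):

$$\mathrm{VIP}_j = \sqrt{\frac{J \sum_r w_{rj}^2\, SSY_r}{SSY_{cum}}},
\qquad
\mathrm{MBVIP}_j = \sqrt{\frac{f \sum_r w_{krj}^2\, SSY_r}{SSY_{cum}}}$$

with $J$ the feature count of a single-block model and $f$ the total
feature count across blocks. Because weights have unit norm per LV (per
block in the multi-block case), two algebraic identities hold on *every*
fit and are asserted in the test suite at $10^{-6}$: the mean of squared
VIPs equals 1, and the total sum of squared MB-VIPs equals $f \times k$.
These identities are what make "VIP > 1" a meaningful informal screen —
but the package's primary significance machinery is permutation-based.

## Permutation inference

`permutation_pvalues` permutes the outcome labels, refits the supplied
per-feature statistic (VIP, MB-VIP, absolute loadings, ...), and reports
$p_j = \#\{stat^{perm}_j \ge stat^{obs}_j\}/n_{perm}$ — at
$n_{perm} = 10{,}000$ a resolution of $10^{-4}$ — followed by
Benjamini–Hochberg FDR adjustment (`bh_fdr`). Two deliberate choices:

* the plain count estimator can return exactly 0; the conservative
  $(c+1)/(n+1)$ variant is available behind `plus_one = TRUE` but off by
  default, keeping the estimator the simple exceedance fraction;
* only the predictor is refitted per permutation. The ssPA transform and
  scaling do not involve $y$, so refitting them under a permuted $y$ would
  reproduce the same matrices at considerable cost.

## The semi-synthetic spike-in benchmark

The benchmark inserts a known signal into otherwise signal-free data:
labels are shuffled (preserving class sizes and all molecule covariances),
then a constant $\alpha$ — a log2 fold change, multiplicative $2^\alpha$
on the raw scale — is added to every member of one *target pathway* in
the new case group only. Detection methods are then scored on whether they
flag the target (`detection_score`: confusion counts at adjusted
$p \le 0.05$, balanced detection rate, rank-AUC of the target against
non-targets).

Because genuinely benchmark-grade multi-omics data cannot ship with a
package, the base data are fully synthetic (`generate_base`): each pathway
has a latent factor per sample and each member molecule is
$\sqrt{\rho}\,f + \sqrt{1-\rho}\,\sigma\varepsilon$, giving exactly
$\rho$ within-pathway correlation in expectation, unit molecule variance
at $\sigma = 1$, near-zero correlation between unrelated pathways, member
overlap between consecutive pathways, and membership spanning all blocks.
Default conditions: 500 balanced samples, 2 blocks, 40 pathways of 20
molecules, 10% overlap, $\rho = 0.5$, $\sigma = 1$, chosen once as a
realistic mid-sized clinical multi-omics study on the log2 scale.

The generator emulates the features the benchmark needs — and nothing
more. Real omics data additionally carry heavy-tailed abundance
distributions, block-specific technical variance, hierarchically nested
and size-heterogeneous pathways, and between-pathway biological
correlation. Passing tests on this generator therefore demonstrate
*method correctness under the stated assumptions*, not expected field
performance on clinical data.

## Numerical and procedural choices

* **NIPALS convergence**: relative score change below $10^{-10}$, at most
  500 iterations; non-convergence yields a warning and the current
  vectors. With a univariate response the inner loop converges in one
  pass.
* **Scaling**: sample standard deviation with denominator $n-1$;
  zero-variance columns are an error instructing the caller to filter.
* **Low-variance filter**: strictly-below-percentile comparison, so
  all-equal variances remove nothing.
* **Imputation** (`lowrank_impute`): iterative truncated-SVD refill,
  rank 10 capped at $\min(N,M)-1$, tolerance $10^{-4}$, observed cells
  never altered; imputation is applied to log2 data before scaling.
* **Coverage**: pathways need `min_coverage` (default 2) mapped molecules;
  below it they are dropped, never an error.
* **Mann–Whitney U**: exact enumeration when both groups have at most 8
  untied values, normal approximation with tie correction otherwise.
* **Fisher majority rule**: combined over *all* member p-values once at
  least 50% pass 0.05; zero p-values floored at the smallest positive
  double with a warning.
* **Ties in model selection**: `select_n_latent` breaks ties toward the
  smaller number of LVs; `recursive_feature_elimination` toward the
  smaller feature set.
* **Latent-variable selection under flat CV curves**: at low effect sizes
  the held-out AUC curve over candidate LV counts can be flat relative to
  fold-assignment noise, making a single 5-fold pass close to a coin
  toss. `select_n_latent` therefore supports `repeats`: the curve is
  averaged over repeated stratified fold assignments before the maximum
  is taken. The packaged benchmark protocol uses 10 repeats.
* **Multi-omics molecules in several blocks**: concatenation keeps the
  first occurrence of a duplicated identifier, with a warning.

## Problem sizes used by the packaged checks

The test-suite benchmarks are sized for a desk-scale run: parameter
recovery and detection use 20 independent simulation seeds at $n = 500$
with 40 pathways, MB-VIP permutation p-values use 200 permutations
(resolution 0.005 against the 0.05 threshold), the univariate power
comparison uses 80 realisations (40 pathways at two effect sizes), and
the permutation-resolution check uses the full 10,000 permutations with
an inexpensive statistic. These sizes are the package's own choices for a
reproducible default run; all of them scale up by changing the
corresponding arguments.

## Known limitations

* No handling of samples missing an entire omics view; all blocks must
  share one sample set.
* Binary and continuous outcomes only; no multi-class encoding.
* No sparse/regularised multi-block variant; feature selection is via
  permutation-filtered importances or recursive elimination.
* kernel-PCA scores have no molecule-level loadings; use the SVD method
  when molecule attribution matters.
* Identifier namespaces are opaque strings: no online identifier mapping
  is performed, so the pathway collection must already use the data's
  identifiers.

## A minimal end-to-end run

```{r example, eval = FALSE}
cfg <- synthetic_config(n_samples = 200, n_pathways = 20, seed = 1)
base <- generate_base(cfg)
sp <- spike_in(base$blocks, base$y, base$collection,
               target_pathway_id = "P07", alpha = 0.8, seed = 2)

fit <- fit_multiview(sp$blocks, sp$y, ncomp = 2,
                     collection = base$collection, sspa_method = "svd")
summary(fit)

mv <- mb_vip(fit)
head(mv[order(-mv$importance), ])

scores <- lapply(fit$sspa_fits, `[[`, "scores")
perm <- permutation_pvalues(
  function(data, y) {
    iv <- mb_vip(fit_multiview(data, y, ncomp = 1))
    setNames(iv$importance, paste0(iv$block, ".", iv$feature))
  },
  scores, sp$y, n_perm = 1000, seed = 3)
head(perm[order(perm$p_adj), ])
```
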