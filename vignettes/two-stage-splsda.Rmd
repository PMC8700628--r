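---
title: "Methods: two-stage sparse PLS-DA for CD vs UC from mucosal RNA-seq"
author: "ibdclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage sparse PLS-DA for CD vs UC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdclass)
```

# The problem

Crohn's disease (CD) and ulcerative colitis (UC) are the two major
inflammatory bowel disease subtypes. They overlap clinically and
endoscopically, yet long-term management differs, so a molecular classifier
built on biopsy RNA-seq is attractive. The difficulty is a sampling
confound: in a typical colonoscopy cohort the *normal* (non-inflamed)
biopsies come predominantly from the terminal ileum in CD patients and from
the rectum in UC patients. A naive classifier trained to separate CD from UC
therefore partly learns gut *segment*, not disease. `ibdclass` implements a
two-stage procedure that first identifies and removes the strongest
normal-tissue (segment-confounded) discriminators and only then trains a
sparse classifier of inflamed CD versus inflamed UC.

# The model

## Preprocessing

Counts are filtered, normalized and transformed the way a standard
`edgeR`-based pipeline would, and `edgeR` performs these steps behind the
package's functions:

* `filterLowCounts()` keeps genes whose CPM exceeds the cutoff implied by a
  count of `minCount` (default 10) at the median library size in at least
  *k* samples, where *k* is the smallest group size, and whose total count
  is at least `minTotal` (default 15).
* `tmmFactors()` computes trimmed-mean-of-M-values factors (M-trim 0.30,
  A-trim 0.05, precision weighting, reference sample by the upper-quartile
  rule) rescaled to geometric mean 1; effective library size = raw depth
  times factor.
* `logCPM()` returns `log2` counts per million on effective library sizes
  with an average prior count of 2, rescaled per sample in proportion to
  depth. The prior keeps every value finite; it also means that exact CPM
  scale invariance holds only in the limit of a vanishing prior.

Normalization is computed once on all samples jointly, so stage-1 and
stage-2 expression values are on a common scale; per-stage renormalization
was rejected for that reason.

## PLS-DA

For two classes, partial least-squares discriminant analysis encodes the
labels as a centered two-column indicator matrix $Y$ and the preprocessed
expression matrix as $X$ (samples in rows; genes centered and, by default,
scaled to unit variance). Each component $h$ finds the unit weight vector
$w_h$ maximizing the covariance between $X_{h-1} w_h$ and the projected
indicator — for two classes this is the leading left singular vector of
$X_{h-1}^\top Y_{h-1}$, equivalently the (scaled) between-class mean
difference direction of the deflated matrix. Scores are $t_h = X_{h-1}
w_h$; both $X$ and $Y$ are deflated by their regression on $t_h$
(regression-mode deflation), which makes score columns exactly orthogonal.
Prediction uses the regression coefficients $B = W (P^\top W)^{-1} C^\top$:
`max_score` assigns the class with the largest predicted indicator value
(the default, matching the common toolkit default), `centroid` the class
with the nearest mean training score vector; exact ties go to the
alphabetically first label so results are platform-stable.

## The pruning statistic

Stage 1 fits a dense PLS-DA of normal CD versus normal UC (default 2
components) and scores each gene by the absolute projection of its loading
vector onto the unit vector connecting the two class mean score vectors in
latent space:
$$s_g = \left| \sum_h p_{gh} \, d_h \right|, \qquad
d = \frac{\bar t^{(A)} - \bar t^{(B)}}{\lVert \bar t^{(A)} - \bar t^{(B)} \rVert}.$$
Genes with large $s_g$ are the strong normal-tissue discriminators — in
this design largely segment-confounded — and `pruneTopFraction()` removes
the top `floor(fraction * n)` of them (ties broken by gene identifier so
the kept set is reproducible). The projection is taken in latent space; a
gene-space reading of "the direction connecting the class means" is
possible but was not adopted, because the latent-space direction is the one
the fitted model actually uses to separate the classes.

The *trench table* reports, for fractions 1/4, 1/2 and 3/4, the
cross-validated error of (a) the normal-vs-normal classifier and (b) the
inflamed-vs-inflamed classifier, each restricted to the genes kept at that
fraction. For (a), scoring and pruning are re-done inside every training
fold (`prunedPlsdaFitter()`), so the reported error is leakage-free. For
(b) the pruning scores derive from the normal samples, which are disjoint
from the cross-validated inflamed samples, so the gene restriction leaks no
test-label information. Heavier pruning removes more of the genes that
separate normal CD from normal UC, so the stage-1 error should rise with
the fraction — the package's acceptance suite checks this monotone pattern
on simulated cohorts. One caveat observed in simulation: once pruning
removes essentially *all* discriminative genes, the classifier degenerates
toward the majority class and, with imbalanced classes (65 vs 13 normals),
the overall error floors at the minority fraction rather than 0.5; the
monotone pattern is therefore a property of the regime where residual
signal remains.

## Sparse PLS-DA and tuning

`fitSPLSDA()` soft-thresholds each component's dense weight vector at the
magnitude of its (keepX+1)-largest absolute entry, so exactly `keepX`
genes keep nonzero weight (ties at the cut broken by gene identifier, with
an infinitesimal weight retained so the support size is exact), then
renormalizes to unit length. Deflation uses the full regression loadings,
preserving exact score orthogonality; the *reported* loadings are masked to
the support so unselected genes are exact zeros, and with `keepX` equal to
the gene count the sparse fit reproduces the dense fit identically.

`tuneKeepX()` performs the sequential (greedy) per-component search:
component 1's keepX minimizes the mean repeated-CV error over the grid,
then stays fixed while component 2 is searched, and so on. The criterion
defaults to the balanced error rate because the inflamed classes (29 CD vs
20 UC) are mildly imbalanced; ties go to the smaller keepX. Parsimony has a
visible consequence on strongly separable data: when a 5-gene model already
attains minimal CV error, the search stops there, so the tuned signature
can be much smaller than the true discriminative set. The grid defaults to
1..300 per component; desk-scale runs pass a sparse grid.

## Cross-validation

All error estimation uses stratified k-fold CV (default 5-fold) repeated
with independent random splits. Stratification — dealing each class
round-robin into folds after a seeded shuffle — is a deliberate choice the
protocol itself does not specify: with a 13-sample class, unstratified
5-fold splits can produce test folds missing a class entirely, leaving the
balanced error undefined. Within a repeat, held-out predictions are pooled
across folds before computing the overall error rate (OER, misclassified /
total) and balanced error rate (BER, mean per-class error), so unequal fold
sizes are weighted by sample; repeats are then averaged. Any feature
selection inside a fitter (pruning, sparse selection) is redone inside each
training fold. In the *final* evaluation the tuned keepX values are held
fixed while each training fold re-selects its genes; nesting the entire
grid search inside every fold was considered and rejected — it multiplies
cost by the grid size while the fixed hyperparameter leaks no per-fold test
information (gene identity is still re-estimated per fold).

The stage-2 dense component count is chosen as the minimizer of the mean CV
*overall* error over 1..`stage2NcompMax` (default 4), ties toward fewer
components; the keepX tuning criterion is balanced error by default. Both
criteria are exposed in `analysisConfig()`.

# The simulator

`simulateCounts()` draws counts from a Gamma–Poisson (negative-binomial)
model, $\mathrm{var} = \mu + \phi \mu^2$ with a single dispersion $\phi$
shared across genes (default 0.1, a typical bulk RNA-seq value; a single
$\phi$ keeps recovery analysis interpretable). Gene baselines are
$\log_2$-normal (mean 4, sd 2, i.e. a median count of ~16 with a long
right tail); per-sample depth factors are log-normal (sd 0.3, about
±35% depth variation, enough to exercise TMM). Class sizes default to the
study cohort: 29 CD-inflamed, 65 CD-normal, 20 UC-inflamed, 13 UC-normal,
on a 2000-gene universe (the cohort's full universe of 19,596
protein-coding genes is available by setting `nGenes`; 2000 keeps the
packaged benchmarks fast without changing the qualitative structure).

Three disjoint planted sets mimic the cohort's variance structure:

| set | default size | default \|log2FC\| | affects |
|---|---|---|---|
| inflammation | 200 | 2.0 | both inflamed classes, identically |
| disease | 20 | 1.5 | inflamed CD vs inflamed UC |
| segment | 100 | 2.0 | normal CD vs normal UC |

Within each set half the genes go up and half down (for the between-class
sets, "down" means up in the opposing class), which keeps library
composition roughly balanced so TMM is exercised rather than stressed. The
inflammation set is large and strong so the first principal component
tracks inflammation, with disease separation on later components. Because
disease genes are *null in normal tissue*, stage-1 pruning removes each of
them at roughly the background rate — about half at the default fraction.
That is a property of the design being emulated, not an artifact: the
pruning stage pays a deliberate price in recoverable signal to remove the
segment confound. Recovery of the planted signature should therefore be
judged against the genes still available after pruning.

The simulator does **not** model gene–gene correlation, batch effects,
gene-length effects, isoform structure, or per-class dispersion and depth
differences. Passing tests on simulated data show that the pipeline's
machinery behaves as specified under the assumed generative model; they do
not certify performance on real cohorts, where correlated expression
programs and unmodeled heterogeneity make classification harder.

# Numerical choices

* Constant genes receive a scale of 1 (not 0) so unit-variance scaling
  never divides by zero in a CV fold.
* PLS weight orientation is fixed by the sign of the first class's
  indicator loading; PCA component signs by the largest-magnitude loading.
  Both make outputs identical across linear-algebra backends.
* `floor()` for the prune count, lexicographic tie-breaks for pruning and
  soft-threshold cuts, and alphabetical tie-breaks in prediction make every
  discrete decision deterministic.
* All randomness flows from integer seeds; CV repeat $r$ uses
  `seed + r - 1`, and the workflow derives fixed offsets per stage, so any
  stage can be reproduced in isolation.
* A degenerate component (no covariance left to deflate) raises an error
  rather than returning zero scores.

# Problem sizes in the packaged checks

The package's tests and the acceptance script run at benchmark scale,
chosen so the full suite completes on a laptop-class single core: simulated
cohorts of 2000 genes (400–600 in unit tests), a keepX grid of
{5, 10, 20, 50, 100}, tuning with 10–20 CV repeats and final evaluation
with 50–100 repeats. The statistical conditions (class sizes, planted
effect sizes, dispersion) are those described above; only the grid
resolution and repeat counts are reduced relative to the full protocol
(grid 1..300, 100 repeats throughout), which affects estimation variance
but not the contracts being checked.

# Known limitations

* Two-class PLS-DA only; no multiclass or orthogonal-PLS variants.
* The pruning statistic is the latent-space loading projection; alternative
  statistics (t-scores, fold changes) are out of scope.
* No gene-length normalization or batch correction.
* The final error estimate fixes the tuned keepX across folds (see above);
  a fully nested search would give a marginally more conservative estimate.
* Real-cohort headline numbers depend on the deposited raw data and its
  alignment pipeline and are not reproduced by the simulator.
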