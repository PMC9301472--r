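---
title: "Methods: sparse hierarchical graph representations for severity prediction"
author: "severityNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse hierarchical graph representations for severity prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(severityNet)
```

## The problem

Resting-state fMRI yields, for each subject, a functional brain network: an
$n \times n$ matrix of statistical dependencies between the average BOLD
signals of $n$ regions of interest (ROIs). severityNet predicts a
*continuous* clinical score — e.g. a calibrated autism symptom-severity
score — from such a network. Regression on a graph is harder than
case–control classification: the model must rank subjects along a
behavioural continuum from edge-weight patterns that vary across
acquisition sites and demographics.

The package implements the full chain: connectivity estimation and
harmonization, a graph neural network that learns its own node features and
coarsens the graph hierarchically, nested cross-validated training, and two
interpretation tools (a three-level correlation analysis of the learned
node embeddings, and gradient-saliency edge attribution). A seeded
synthetic-cohort generator makes every stage testable without access to any
clinical data.

## Connectome construction

Given a $T \times n$ time-series matrix with demeaned columns
$\tilde t_i$, the package offers two edge definitions:

* **Pearson correlation**
  $c_{ij} = \tilde t_i^\top \tilde t_j \big/ \sqrt{(\tilde t_i^\top \tilde t_i)(\tilde t_j^\top \tilde t_j)}$,
  the field's default; and
* **Tikhonov-regularized precision** $P = (C + \rho I)^{-1}$ with
  $C = \frac1T \tilde T^\top \tilde T$ and $\rho = 0.1$ by default, which
  damps indirect (shared-neighbour) connections. The empirical covariance
  uses $1/T$ normalization; `tikhonovConnectivity(partialCor = TRUE)`
  exposes the partial-correlation sign convention
  $-P_{ij}/\sqrt{P_{ii}P_{jj}}$, but the default uses the precision matrix
  itself, matching the pipeline the model was designed around.

Each matrix is then **proportionally thresholded**: the diagonal is zeroed
and only the $m = \lfloor s \cdot n(n-1)/2 \rfloor$ upper-triangle entries
of largest *absolute* value are kept, at sparsity $s = 0.05$ by default.
Ranking by magnitude but keeping the signed weights preserves
anticorrelation information. Ties at the cutoff are broken by lexicographic
$(i,j)$ position so results are platform-independent. The retained entries
are **standardized per subject** to zero mean and unit *population*
standard deviation (zeros stay exactly zero); the scope of the
normalization — retained edges only, per subject, after the diagonal is
zeroed — is a package convention, stated here because reasonable
alternatives exist.

**Harmonization.** Multi-site data carry site and demographic effects.
`residualizeCovariates()` fits, per retained edge position, an
ordinary-least-squares regression on an intercept, one-hot site indicators
(first level dropped), age, and a 0/1 sex indicator, and replaces all
values by their residuals. Fitting on the whole sample mirrors
harmonization applied before training; passing training-fold indices as
`fitRows` gives the leakage-free variant. Empirical-Bayes batch
harmonization (ComBat-style shrinkage) is intentionally out of scope;
existing implementations can be applied upstream.

## The model

The network composes four stages (widths below are the defaults in
`modelConfig()`).

**1. Edge-to-edge (E2E) feature extractor.** Two stacked E2E layers embed
edge features over the line graph of the connectivity matrix with a
cross-shaped kernel — a row kernel $r^{l,a,b} \in \mathbb R^n$ and a column
kernel $c^{l,a,b} \in \mathbb R^n$ per (input map $a$, output map $b$)
pair:
$$f^{l+1,b}_{ij} = \mathrm{lReLU}\Big(\sum_{a=1}^{d_l}\sum_{k=1}^n
  r^{l,a,b}_k f^{l,a}_{ik} + c^{l,a,b}_k f^{l,a}_{kj}\Big),$$
with leaky slope $1/3$. The input is the single map $f^1 = g$.

**2. Edge-to-node (E2N) aggregation** turns edge features into node
features: $e^{b}_i = \mathrm{lReLU}\big(\sum_a \sum_k w^{a,b}_k
f^{L,a}_{ik}\big)$, giving an $n \times d$ node-feature matrix. The feature
width $d$ is a free parameter (default 32): the architecture fixes the
layer *pattern*, not the width, so $d$ plays the role filter counts play in
convolutional networks.

**3. Adjacency embedding.** The pooling stage needs a binary graph. Three
variants derive logits $R$: `identity` uses the input matrix itself
($R = g$); `e2e` applies one extra E2E kernel to the last hidden edge
tensor; `averaging` takes the mean of the last layer's hidden edge maps. An
edge exists where $\mathrm{sigmoid}(R_{ij}) \ge 0.5$, i.e. $R_{ij} \ge 0$,
with the tie counting as an edge; the result is symmetrized by logical OR
because the GCN propagation below assumes a symmetric adjacency.

**4. Self-attention top-$k$ pooling.** Each of the two pooling layers
scores nodes with a two-GCN stack,
$S = \mathrm{sigmoid}(\mathrm{GCN}(\mathrm{lReLU}(\mathrm{GCN}(X, A; W^0)), A; W^1))$
where $\mathrm{GCN}(X, A; W) = \tilde D^{-1/2}\tilde A\tilde D^{-1/2} X W$
with $\tilde A = A + I$, keeps the $\lceil n_l/2 \rceil$ highest-scoring
nodes (ties to the lowest original index), and gates the survivors with a
residual attention update $X' = \dot X \odot \dot S + \dot X$. The score
stack's hidden width is $p = 1$. A readout
$z = \sum_l [\,\mathrm{mean}_i\, x^l_i \,\|\, \max_i x^l_i\,]$ sums the
per-layer mean–max concatenations (so $z \in \mathbb R^{2d}$), and a dense
head of sizes 128 and 64 (leaky ReLU, biases everywhere) produces the
scalar prediction. Summing rather than concatenating across layers, and
reading the hyperparameter $L = 2$ as the number of pooling layers with a
fixed two-GCN score stack, are the package's resolutions of genuinely
ambiguous architectural choices; both are stated here so alternatives can
be evaluated deliberately.

### Gradients and the hard threshold

All gradients are derived analytically and implemented twice: a reference
R path (`modelForward` / `modelBackward`) and a compiled RcppArmadillo path
used for training; the two are cross-checked to machine precision in the
test suite, and parameter gradients are verified against central finite
differences.

The 0.5 threshold in the adjacency embedding is piecewise constant, so its
exact derivative is zero almost everywhere. Two conventions are provided:

* `straight` (training default): the backward pass substitutes the sigmoid
  of the logits for the threshold (a straight-through estimator), so the
  `e2e` embedding kernels receive gradient;
* `detach`: the binary adjacency is treated as a constant. This is the
  exact local gradient and is what `saliencyMap()` uses, since a saliency
  map should report the true local derivative — which is also what finite
  differences see away from the threshold boundary.

## Training

`trainConfig()` defaults follow the reference recipe: SGD with momentum
0.9, weight decay $10^{-4}$ (added to the gradient, i.e. the gradient of a
$\frac{\lambda}{2}\|\theta\|^2$ penalty), mean-squared-error loss,
mini-batches of 8, He initialization (zero-mean Gaussians with variance
$2/\mathrm{fan\_in}$, zero biases), and a cosine schedule
$\alpha_t = \tfrac12(1 + \cos(t\pi/T))\,\alpha_0$ decaying from
$\alpha_0 = 10^{-5}$ to zero over $T = 1000$ epochs. Evaluation uses
nested cross-validation: 5 seeded outer folds; within each outer training
set a seeded 90/10 split drives per-epoch model selection (the epoch with
the best inner-validation MAE is kept — the selection rule itself is a
package choice). Out-of-fold predictions are pooled across folds and
summarized by MAE, Pearson $r$, and the two-sided $p$-value from the exact
$t$-transform of $r$ with $N-2$ degrees of freedom. Pooling (rather than
averaging per fold) matches how prediction scatter is usually reported.
Fold assignment shuffles uniformly; stratification by site or score is not
applied. Targets are used on their natural scale. `clipNorm` optionally
rescales batch gradients to a maximum L2 norm — momentum SGD on
small cohorts can otherwise diverge at learning rates well inside the
useful range; clipping is off by default.

All arithmetic is double precision, including training.

## Interpretation

**Three-level correlation analysis.** For each subject, the E2N output
$X_{nf} \in \mathbb R^{n \times d}$ (domain 1) is related to eight
graph-theory nodal measures $X_{gm} \in \mathbb R^{n \times 8}$ (domain 2):
degree, clustering coefficient, local efficiency, betweenness, eigenvector
centrality, subgraph centrality, flow coefficient, and $k$-core number,
computed on the binarized thresholded graph ($|w| > 0$; several of these
measures are only standard for binary graphs). The flow coefficient — for
which no canonical formula citation exists — follows the
brain-connectivity-toolbox convention: the fraction of a node's neighbour
pairs *not* directly connected ($1 -$ clustering on simple graphs); this
definition is flagged as an interpretation. The three levels are:

1. $r_i = \max_j \mathrm{corr}(x^i_{gm}, x^j_{nf})$ — best single
   embedding dimension per measure;
2. $r^{c1}_i = \max_w \mathrm{corr}(x^i_{gm}, X_{nf} w)$ — the multiple
   correlation, $\sqrt{R^2}$ of regressing measure $i$ on all embeddings;
3. $r^{c2}$ — the first canonical correlation between the two domains,
   computed from the SVD of the whitened cross-covariance
   $\Sigma_{11}^{-1/2}\Sigma_{12}\Sigma_{22}^{-1/2}$.

By construction level 1 $\le$ level 2 $\le$ level 3 (nested optimization
spaces); the test suite asserts this on random instances. A ridge
$\varepsilon = 10^{-8}$ stabilizes the within-set covariances since $n$ can
be close to $d$; the exact identities (level 2 $= \sqrt{R^2}$, self-CCA
$= 1$) hold with the ridge off. Analysis is per subject, with
distributions across subjects summarized as mean $\pm$ sd; pooling nodes
across subjects is a conceivable alternative reading that the per-subject
API deliberately avoids.

**Saliency.** The partial derivative of the prediction with respect to
every input entry, computed analytically at the model's actual
(preprocessed) input and symmetrized as $(PD + PD^\top)/2$ since edges are
undirected. Per-subject maps are averaged element-wise into a group map;
edges are ranked by $|PD|$ and the top fraction (default 10%, read as "top
10% of edges by magnitude") reported as a `region1, region2, pd_value`
table.

## The synthetic cohort generator

`simulateCohort()` emulates what the method assumes about real data: a
cohort of symmetric connectivity matrices in which a sparse set of edges is
linearly coupled to a continuous score, plus additive site offsets and
age/sex effects on the score. In direct-matrix mode, null edges are
standard normal and the $s$ planted edges get inflated magnitudes
($\pm(4 + |N(0, 0.5)|)$, sign random per subject-edge) so they survive 5%
thresholding with near certainty; in time-series mode, matrices come from
the full Pearson pipeline over multivariate normal series with
block-community covariance (within-block correlation 0.35, between 0.05).
The score couples to the *preprocessed* edge values — the quantity the
model actually sees — so the planted model is exactly linear in the model
input:
$y = \mu + \sum_{(i,j) \in \mathrm{supp}} W^*_{ij} g_{ij} + \text{site} +
\text{age} + \text{sex} + \varepsilon$.
When `noiseSd` is `NA`, $\sigma$ is set from the empirical signal variance
so the signal accounts for exactly `signalFrac` of total variance.

Defaults are the package's reference recovery conditions: $N = 300$
subjects, $n = 30$ ROIs, $s = 15$ planted edges, signal fraction 0.64
(hence a theoretical correlation ceiling of $\sqrt{0.64} = 0.8$ between
score and signal), covariate effects zero so the fraction is exact,
target mean 6 with weight scale $\beta = 0.5$, echoing a severity score's
1–10 range. Ages are uniform on [7, 30] and sex Bernoulli(0.5),
echoing a developmental cohort without copying any real demographics.

What the generator does **not** emulate: hemodynamics, motion artifacts,
site effects on the edges themselves (only on the score, unless planted
explicitly), heavy-tailed edge distributions, and spatial autocorrelation
between ROIs. Passing the recovery experiment therefore demonstrates that
the implementation can recover a known sparse linear signal end to end —
not that the architecture captures real fMRI structure.

## The recovery experiment

`recoveryExperiment()` is the package's end-to-end validation and the
computation behind `scripts/acceptance.R`: simulate the reference cohort,
preprocess at 5% sparsity, train with identity adjacency under nested
5-fold CV, and measure pooled held-out MAE and Pearson $r$, the
predict-the-mean baseline MAE, and the precision of the top-$s$
group-saliency edges against the planted support (chance rate
$s/\binom{n}{2} \approx 0.034$). Saliency for each subject is computed with
the fold model that held that subject out.

The experiment's training settings are scaled to the problem: $d = 8$
feature maps, 200 epochs, and $\alpha_0 = 10^{-3}$ with `clipNorm = 25`.
The reference recipe's $\alpha_0 = 10^{-5}$ over 1000 epochs is tuned to
cohorts and architectures an order of magnitude larger; on the $n = 30$
synthetic cohort it underfits badly within 200 epochs, while $10^{-3}$
converges in tens of epochs and relies on clipping plus best-validation
selection for stability. These values were fixed once from the training
loss of a pilot run and are function arguments, not constants.

## Numerical choices and degenerate inputs

* Thresholding: `floor` for the retained-edge count; ties by lexicographic
  position; an all-zero matrix retains nothing. Whether ties at the cutoff
  belong in or out has no canonical answer; the stated rule is simply
  deterministic.
* Standardization requires $\ge 2$ retained edges with spread; constant
  retained values raise an error rather than dividing by zero.
* Pooling: $k = \lceil \mathrm{ratio} \cdot n_l \rceil$, so one node always
  survives; after two half-ratio layers $\lceil\lceil n/2\rceil/2\rceil$
  nodes remain.
* `sigmoid(0) = 0.5` counts as an edge; a standardized matrix's zero
  diagonal therefore maps to self-edges in the identity embedding, and the
  GCN's added self-loop makes degrees strictly positive either way.
* Graph measures on disconnected graphs: path-based measures are computed
  per component; eigenvector centrality lives on the largest component
  (unit 2-norm) and is zero elsewhere; isolated or degree-1 nodes get zero
  clustering, efficiency and flow.
* Finite-difference verification of gradients is only meaningful where the
  piecewise-smooth network does not switch a discrete branch (threshold,
  top-$k$ selection, readout argmax, leaky-ReLU kink) inside the
  difference interval; the tests detect and exclude branch switches.

## Problem sizes

The test suite and acceptance script run at deliberately modest scale,
chosen as the smallest sizes at which every claim is still meaningfully
exercised: layer oracles at $n \le 8$, $d \le 3$; recovery at $N = 300$,
$n = 30$, 200 epochs; determinism at $N = 40$, 20 epochs. The
implementation itself has no small-$n$ assumptions — the `nROIs`, `nMaps`
and epoch parameters scale to atlas-sized problems (90–400 ROIs), with
compute growing as $O(d^2 n^2)$ per subject-pass for the extractor.

## Known limitations

* Only the linear-regression part of multi-site harmonization is built in;
  empirical-Bayes shrinkage must come from upstream tools.
* The model is not permutation-invariant for fixed kernels (kernels are
  position-indexed); node order must be consistent across subjects — the
  equivariance test documents exactly this.
* The straight-through estimator is a heuristic; for the `e2e` embedding
  variant, gradient quality through the threshold is not guaranteed.
* Dynamic (sliding-window) connectivity, population-graph models,
  classification heads and hyperparameter search automation are out of
  scope.
```
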