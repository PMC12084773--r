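---
title: "Symptom networks from three-wave panel data: models, calibration and design choices"
author: "panelnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symptom networks from three-wave panel data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelnet)
```

## What the package models

`panelnet` analyzes co-occurring internet-addiction (IA) and
psychological-distress symptoms measured repeatedly in the same cohort.
Its node layout is fixed by `make_node_scheme()`: the six subscales of
Young's Internet Addiction Test (IAT; 20 items rated 1–5, allocated
5/5/3/2/3/2 to salience, excessive use, neglect work, anticipation, lack
of control, and neglect of social life) and the 21 items of the DASS-21
(each rated 0–3, seven items per depression/anxiety/stress subscale).
Subscale scores are item sums, so an IA node with $k$ items is bounded by
$[k, 5k]$; a 20-item IAT total therefore spans 20–100 (a "0–100" range is
sometimes quoted for this instrument, but it is arithmetically impossible
with 1–5 item scoring, and the package uses 20–100 throughout).

Two complementary network models are estimated.

**Cross-sectional networks.** Within a wave, the conditional association
structure is a Gaussian graphical model: edge weights are regularized
partial correlations obtained from an $\ell_1$-penalized precision
matrix,
$$\hat\Theta(\lambda) = \arg\max_\Theta\; \log\det\Theta -
\mathrm{tr}(S\Theta) - \lambda \sum_{i\neq j} |\Theta_{ij}|,$$
with $w_{ij} = -\hat\Theta_{ij}/\sqrt{\hat\Theta_{ii}\hat\Theta_{jj}}$.
The penalty is chosen on a path of 100 log-spaced values (from the
largest absolute off-diagonal correlation down to 1/100 of it) by the
extended BIC,
$$\mathrm{EBIC}_\gamma = -2\ell(\hat\Theta) + E\log n + 4E\gamma\log p,$$
where $E$ counts selected edges and $\gamma = 0.5$ is the usual
conservative default. The graphical-lasso solver is implemented in
compiled code (block coordinate descent on the covariance estimate with
warm starts along the path); penalization applies to off-diagonal
entries only.

**Cross-lagged panel networks (CLPN).** Between two waves, the directed
edge $i \to j$ is the coefficient of node $i$ at wave $t$ in an
$\ell_1$-penalized regression of node $j$ at wave $t+1$ on *all* wave-$t$
nodes, with every column z-scored within its wave. The diagonal holds
autoregressive paths. The lasso objective is the standard
$(1/2n)\|y - X\beta\|^2 + \lambda\|\beta\|_1$ on fully standardized data,
solved by cyclic coordinate descent on the Gram matrix.

A note on the penalty scale: descriptions of CLPN analyses sometimes
quote a single tuning-parameter value (for instance 0.5) without fixing
the objective convention, and on the standardized scale used here such a
value would zero out essentially every path. `fit_clpn()` therefore
defaults to per-response 10-fold cross-validation
(`lambda_mode = "cv"`, deterministic fold assignment from the seed) and
exposes `lambda_mode = "fixed"` for sensitivity analyses at any fixed
value. On calibrated synthetic cohorts of $n \approx 2500$ the CV choice
retains roughly 160–200 nonzero cross-lagged edges out of 702, the
sparsity regime typical of reported CLPNs of this size.

## Centrality indices

For undirected networks, one-step expected influence is the signed row
sum $\mathrm{EI1}(i) = \sum_j w_{ij}$, and
$\mathrm{EI2}(i) = \mathrm{EI1}(i) + \sum_j w_{ij}\,\mathrm{EI1}(j)$
propagates neighbours' influence through the connecting edge. For CLPNs,
out- and in-expected influence (OEI/IEI) are signed sums of outgoing and
incoming cross-lagged coefficients; with the default
`scope = "cross_construct"` only paths crossing the IA/distress boundary
count, which isolates the between-construct dynamics (autoregressive
paths are always excluded; `scope = "all"` is available for
sensitivity). Bridge expected influence restricts the sum to
boundary-crossing edges; the two communities are the binary IA-versus-
distress split, not the four-way construct split, because the bridge
question is how the two instruments connect. BEI sums *outgoing* edges
by default — bridges read as predictors — with `"in"` and `"both"`
conventions implemented since published usage varies. Two-step
BEI adds influence transmitted through any intermediate node:
$\mathrm{BEI2}(i) = \mathrm{BEI1}(i) + \sum_k B_{ik}\,\mathrm{BEI1}(k)$.
All indices are reported raw; `standardize_centrality()` provides the
z-scored view used in centrality plots.

## The synthetic cohort and its calibration

Because raw participant data of the motivating study design are not
publicly deposited, the package ships a generator whose output has the
statistical properties the estimators assume, with known ground truth:

1. `sample_true_ggm()` draws a sparse partial-correlation truth. Edges
   are placed uniformly at random; magnitudes are uniform in a
   requested band (default 0.15–0.35) and predominantly positive
   (`prob_positive = 0.8`), as is typical of symptom networks. The
   precision matrix $I - P$ is checked for positive definiteness and the
   draw is shrunk or rejected if the band is too aggressive. A
   conditioning floor (smallest precision eigenvalue at least 0.1 by
   default) additionally rejects near-singular truths: those imply
   marginal correlations approaching 1, a regime bounded Likert-type
   scores cannot produce.
2. `sample_true_clpn()` draws the lag-1 transition matrix: autoregressive
   diagonal in 0.4–0.6, sparse cross effects (default density 0.05,
   magnitudes 0.15–0.3, mostly positive), optional forced edges (e.g. a
   planted depression-to-IA path), spectral radius kept below 0.95.
3. `simulate_panel()` draws wave 1 from the GGM-implied covariance and
   iterates $X_{t+1} = B^\top X_t + \varepsilon$. In ordinal mode each
   latent column is discretized by `discretize_likert()`.

The discretizer is a monotone rank binning: a discretized normal on the
node's integer levels is moment-matched to the target mean/SD (a
Nelder–Mead fit refined by a one-dimensional root find so the implied
mean hits the target), and its cumulative probabilities cut the
empirical quantiles of the latent column. Ties map to the same level and
ordering is preserved, so the latent correlation structure survives up
to the usual ordinalization attenuation.

Default targets (`default_calibration()`) emulate a large Chinese
college-student cohort over three waves: per-subscale IAT means/SDs at
each wave (baseline total ≈ 44.9), and a common per-item distress target
derived from DASS totals (baseline 11.27, SD 9.49) via the
equal-correlation identity
$\mathrm{Var}(\text{total}) = k\sigma^2(1 + (k-1)\rho)$ with $\rho$
implied by the scale's Cronbach $\alpha$ (0.93–0.95), giving per-item
SDs near 0.65–0.70. The generator matches *marginal* node moments; total-
score SDs additionally depend on the inter-node correlation truth, which
is a free parameter of the simulation, so scale-total SDs are close to
but not pinned at any particular cohort's values.

What passing tests on this cohort do **not** show about real data:
marginals are discretized normals rather than genuinely skewed Likert
response processes; missingness is injected MCAR only
(`inject_missingness()`), and the pipeline analyzes complete cases —
multiple imputation is deliberately out of scope; measurement error,
attrition mechanisms and cohort heterogeneity are absent.

## Robustness machinery

`bootstrap_edges()` resamples participants with replacement (default
1200 draws) and re-runs the frozen estimator — including re-running
EBIC selection or per-response CV each draw. Edge CIs are empirical
2.5/97.5 percentiles; `bootstrap_difference_test()` flags pairs whose
bootstrapped difference CI excludes zero. `case_drop_stability()`
subsamples without replacement over a drop grid (default 0.05–0.75 in
steps of 0.05) and reports the CS coefficient: the largest drop
proportion at which at least 95% of subsamples correlate at least 0.7
with the full-sample centrality, with all smaller proportions also
qualifying (0 if none does); 0.25/0.5 are the usual
acceptable/good bands. `network_comparison_test()` permutes either group
labels (independent groups) or, by default for wave comparisons of one
cohort, swaps each participant's two records with probability 1/2, and
reports the maximum edge difference (M), the global-strength difference
(S), add-one permutation p-values, and Holm-corrected per-edge p-values
referred to the max-difference null. `power_simulation()` re-estimates
networks from data simulated under a known truth across a grid of sample
sizes and reports sensitivity, specificity and true-versus-estimated
edge-weight correlation.

## Numerical choices

* Graphical-lasso convergence: maximum element change of the working
  covariance below $10^{-6}$; inner lasso tolerance one-tenth of that.
  Edges are "present" iff $|\hat\Theta_{ij}| > 10^{-8}$ after
  convergence. Exact zeros arise from soft thresholding, not rounding.
* Lasso coordinate descent: convergence when the largest coefficient
  change in a sweep is below $10^{-7}$; coefficients below $10^{-8}$ are
  stored as exact zeros. Inside cross-validation folds a looser
  $10^{-4}$ tolerance is used for scoring only; the final refit at the
  selected penalty uses the strict tolerance.
* CV path: 100 log-spaced penalties per response from
  $\lambda_{\max} = \max_j |x_j^\top y|/n$ down to $10^{-3}\lambda_{\max}$;
  the CV-minimum is selected.
* Every stochastic operation takes one integer seed and restores the
  caller's RNG state; bootstrap, permutation and fold assignments are
  deterministic functions of (data, configuration, seed).
* Graphical-lasso edge sets are *not* exactly nested along the penalty
  path: single edges can drop out as the penalty falls. Tests assert the
  monotone trend with tolerance for such dropouts rather than strict
  nestedness.
* Degenerate inputs fail loudly: constant columns are named in the
  error, missing values direct the user to `complete_case_filter()`,
  non-stationary transition truths are rejected.

## The pipeline

`run_full_analysis()` reproduces the full analysis plan on any
conforming panel: descriptives (per-node moments, per-scale totals and
Cronbach $\alpha$); one cross-sectional network per wave with EI1/EI2 —
by default over the six IA nodes, mirroring wave-wise IA symptom
networks, configurable to all 27 via `ggm_nodes = "all"`; paired
network-comparison tests for consecutive wave pairs; CLPNs for
T1→T2, T2→T3 and T1→T3 with IEI/OEI and BEI1/BEI2; and the bootstrap
and case-drop suite for every estimated network. All artifacts carry
the seed and a hash of the analysis-relevant configuration, and a rerun
with the same inputs is byte-identical. Reported problem sizes in the
package's own validation use $n = 500$–5000 with 200 bootstrap draws and
20–50 case-drop iterations per proportion — scaled-down but
structurally identical versions of the defaults (1200 draws, 50
iterations).

## Known limitations

* Pearson correlations (optionally Spearman) feed the graphical lasso;
  polychoric handling of the ordinal scores is not implemented, so
  partial correlations on heavily discretized nodes are attenuated.
* The CLPN is a two-wave conditional model: no random intercepts, no
  contemporaneous residual network, no elastic-net mixing.
* The CS coefficient's grid resolution (0.05) bounds the precision of
  the reported stability value.
* The unpaired permutation scheme assumes exchangeable participants
  across groups; the paired scheme assumes exchangeable wave labels
  within participant under the null. Neither accommodates partial
  overlap between groups.
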