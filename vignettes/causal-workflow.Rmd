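---
title: "Causal analysis of driving behavior and momentary well-being"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal analysis of driving behavior and momentary well-being}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripcausal)
```

## The problem

Observational trip-level data — momentary affect reported before and after
each drive, driving-behavior summaries from in-vehicle sensors, and
contextual trip factors — cannot be analysed with plain regressions if the
question is causal: a correlation between average speed and post-drive
arousal may be driven entirely by pre-drive arousal influencing both.  This
package implements a three-step workflow for such data:

1. **learn** a causal directed acyclic graph (DAG) from the standardized
   trip table by continuous score-based optimization, with temporally
   impossible edges excluded a priori;
2. **identify**, for every edge of the learned graph, a set of covariates
   satisfying Pearl's backdoor criterion;
3. **estimate** each effect by ordinary least squares of the target on the
   source plus the adjustment set, and probe every estimate's robustness
   by re-estimating with an added random confounder.

The variables follow the study design the package emulates: four affect
scores (arousal and valence, before and after driving, measured on 0–100
sliders), three driving-behavior summaries (steering ratio, braking ratio,
sudden events per hour), three trip-dependent factors (length, average
speed, flow), and four predetermined factors (sunlight, weekend, occupants,
commute).

## The structural model behind the simulator

All synthetic data come from a linear structural equation model (SEM): for
node $j$ with parent weight vector $W_{\cdot j}$,

$$x_j = \sum_i W_{ij}\, x_i + \sigma_j\, \varepsilon_j,
  \qquad \varepsilon_j \sim \mathcal N(0, 1),$$

sampled ancestrally in topological order.  Binary flags (weekend,
occupants, commute) are exogenous Bernoulli roots, centred and scaled to
unit variance before feeding children, so that all weights remain on the
SD-per-SD scale.  With `noise = "unit_variance"` the noise scales
$\sigma_j$ are solved recursively so every continuous node has marginal
variance 1; the solve fails (by design, with an error) when a node's
parents already explain variance $\geq 1$.

`sem_table1()` is the package's ground-truth preset: its 15 edges carry
the study's significant standardized effect sizes, its binary prevalences
are the printed ones where available (weekend 0.18, commute 0.24) and 0.30
for occupants (not printed; a plausible share of accompanied trips), and
the four affect nodes carry raw-scale transforms with the printed slider
moments, clipped to 0–100.

Two numerical facts about this preset are worth stating plainly, because
they are properties of the published numbers, not of the implementation:

* **The preset cannot have unit variance everywhere.**  After-driving
  valence has three positively correlated parents (before-valence 0.77,
  before-arousal 0.19, occupants 0.37) whose contributions explain 1.035
  units of variance.  The preset keeps the weights exact — they are the
  quantity of interest — and floors the noise variance at 0.05 there, so
  after-valence has marginal SD $\approx 1.04$.  The node is recorded in
  `$unit_variance_violations`.  Regression estimates of the weights are
  unaffected; only effects measured *after empirically re-standardizing*
  that column shrink by the factor 1.04.
* **Backdoor-adjusted regression estimates total, not direct, effects.**
  For most preset edges the two coincide, but before-arousal reaches
  after-arousal both directly (0.74) and through mediating paths (via
  speed, and via valence), so its total effect is
  $[(I-W)^{-1}]_{ij} = 0.801$.  The package's recovery tests therefore
  check estimates against `sem_total_effects()`, the analytic
  path-weight sum, rather than against the direct weights.

The simulator emulates the joint second-moment structure of a trip table,
plus realistic raw scales.  It does *not* emulate per-driver clustering
(trips are exchangeable), temporal autocorrelation across consecutive
trips, floor/ceiling-induced skew beyond simple clipping, or nonlinear
dose–response.  Passing tests on this twin show that the pipeline recovers
effects *when its assumptions hold*; they cannot certify the linearity or
unconfoundedness of any real data set.

## Structure learning

`notears_fit()` minimizes the penalized least-squares score

$$\frac{1}{2n}\,\lVert X - XW \rVert_F^2 + \lambda_1 \lVert W \rVert_1
  \quad\text{s.t.}\quad
  h(W) = \operatorname{tr}\!\big(e^{W \circ W}\big) - d = 0,$$

where $h$ is a smooth function that vanishes exactly on acyclic supports.
The equality constraint is handled by an augmented Lagrangian: L-BFGS-B
solves each subproblem on the split $W = W^+ - W^-$ (which makes the L1
term linear on the nonnegative orthant), the multiplier is updated by dual
ascent, and the penalty parameter grows geometrically whenever $h$ fails
to shrink by a factor of 4.  Matrix exponentials use dense
scaling-and-squaring (machine precision matters here: the convergence
check is $h \le 10^{-8}$, far below the accuracy of low-order Padé
approximations).

Defaults — $\lambda_1 = 0.1$, pruning threshold $\omega = 0.3$,
$\rho_0 = 1$, $\rho_{\max} = 10^{16}$, escalation factor 10,
$h_{tol} = 10^{-8}$, 100 outer iterations — are the reference algorithm's
customary settings; every one is exposed in `notears_options()`.  Entries
of the forbidden mask are **eliminated from the parameter vector**, not
penalized, so masked edges are zero to the last bit.  The temporal policy
(`temporal_forbidden_set()`) forbids edges into predetermined factors,
edges from after-driving emotions to any earlier stage, and edges from
behavior or trip factors back to before-driving emotions.

Two scale-related design choices deserve a note.  The least-squares score
is sensitive to variable scale; the pipeline therefore always standardizes
its input, which puts effect sizes on the comparable SD-per-SD scale.  At
the same time, standardizing a linear-Gaussian system with comparable
noise levels removes the variance signal this score uses to orient edges
(a standardized two-node system is exactly direction-symmetric).  The
package's structure-recovery benchmark — ten random 10-node, 12-edge SEMs
with weights drawn from $\pm[0.5, 1.5]$, unequal noise SDs in
$[0.5, 1.5]$, $n = 2000$ — therefore runs `notears_fit()` on the SEM's
natural scale, as the reference evaluations of this algorithm do, and the
field-style pipeline relies on the temporal mask to resolve directions
that standardization leaves ambiguous.  On this benchmark the
implementation attains mean edge true-positive rate about 0.9 and mean
structural Hamming distance about 1.3.

## Identification and estimation

`d_separated()` implements blocking semantics as a reachability search
over (node, direction) states — linear in the number of edges — and
`backdoor_sets()` enumerates candidate sets (all subsets of
non-descendants of the source at this problem's scale of 14 nodes),
testing each by d-separation in the graph with the source's outgoing
edges removed.  Both are verified in the test suite against brute-force
oracles: explicit path enumeration with per-path blocking rules, over
*all* 543 DAGs on four labelled nodes and fifty random six-node DAGs.
`minimal_backdoor_set()` returns the smallest valid set, breaking ties
lexicographically, so the pipeline is deterministic end to end.

`estimate_effect()` is ordinary least squares with an intercept; the
confidence interval and two-sided p-value use the t distribution with
$n - |Z| - 2$ degrees of freedom.  Per the study's analysis conventions,
raw p-values are compared against $\alpha = .05$ (a Benjamini–Hochberg
switch exists but is off by default) and no per-driver clustering is
applied (the analysis is at the trip level).  Binary flags are
standardized like continuous columns by default so that all effects share
the SD-per-SD scale; `standardize_binary = FALSE` reverts to per-flag
units.

## Refutation

`refute_random_confounder()` appends an independent standard-normal
column to the adjustment set and re-estimates.  The population coefficient
is unchanged — an exactly orthogonalized column changes nothing at machine
precision, a property the tests assert — so the observed change is pure
finite-sample noise of order $1/n$.  The reported delta is the mean of 20
independent draws; a single draw is itself a noisy quantity.  At the
study's scale of 1638 trips the mean absolute change across all preset
edges is on the order of $10^{-4}$, comfortably below the $10^{-3}$ level
that the analysis treats as "robust".  This perturbation probes sampling
stability and mild misspecification, not unobserved confounding that is
correlated with the regressors — no refuter of this family can.

## Numerical choices and degenerate inputs

* Standardization uses the sample SD ($n-1$); zero-variance or
  all-missing columns are errors naming the column.
* Missingness is handled by complete-case filtering (`drop_incomplete()`),
  logged with a count; no imputation.
* `threshold_graph()` verifies acyclicity of the pruned support and fails
  loudly if a residual cycle survives (possible only when `h_tol` is set
  very loose).
* Nonconvergence of the structure learner raises a typed error carrying
  the best iterate, rather than silently returning a near-cyclic matrix.
* An effect whose source admits no valid backdoor set within the size cap
  is kept in the effect table flagged non-identifiable, never silently
  dropped.
* `simulate_signals()` places braking/steering episodes and injected
  spikes deterministically with idle gaps, so feature extractors can be
  checked against construction-time ground truth exactly (counts) or to
  $10^{-9}$ (ratios).  Sudden-event detection uses threshold-exceeding
  local maxima of |acceleration| and |steering rate| with a 2 s merge
  window (defaults 2.5 m/s² and 90°/s), a reproducible stand-in for the
  unpublished thresholds of the original instrumentation.

## Problem sizes used in the checks

The shipped tests and the reproduction script use: exhaustive 4-node and
fifty 6-node graphs for the oracle equivalences; ten 10-node/12-edge SEMs
at $n = 2000$ for structure recovery; 100 replicates at $n = 5000$ for
parameter recovery; 500 replicates at $n = 1000$ for interval coverage;
and the study's own $n = 1638$ for the robustness bound.  These sizes give
Monte-Carlo error well below the assertion tolerances while keeping a full
run in the minutes range on one core.

## Known limitations

* Linear-Gaussian score and estimator throughout; a heavier-tailed noise
  switch exists in the simulator for robustness experiments, but the
  learner and estimator remain least-squares.
* Single-graph output: no bootstrap over graphs, so graph uncertainty is
  not propagated into the effect intervals.
* Backdoor identification only — no front-door or instrumental-variable
  machinery, and no latent-confounder (ADMG) representation.
* The exhaustive adjustment-set enumeration is exponential in the number
  of nodes; it is instantaneous at 14 variables but not intended for
  hundreds.
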