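# tripcausal

Causal analysis of observational driving data: how momentary well-being
(arousal and valence, self-reported on 0–100 sliders before and after each
trip) interacts with driving behavior (steering, braking, sudden events)
under trip-dependent factors (length, speed, flow) and predetermined
factors (sunlight, weekend, occupants, commute).

Correlations in such data are riddled with confounding — calm drivers
drive differently *and* arrive differently — so the package implements a
three-step causal workflow over a trip table of standardized variables:

1. **Structure learning.** A causal DAG is learned by continuous
   optimization of the penalized least-squares score
   ½n⁻¹‖X − XW‖²_F + λ₁‖W‖₁ subject to the smooth acyclicity constraint
   h(W) = tr(e^{W∘W}) − d = 0 (augmented Lagrangian, L-BFGS-B), with
   temporally impossible edges (e.g. post-drive emotion → pre-drive
   emotion, anything → predetermined factor) held at exactly zero.
2. **Identification.** For each edge X → Y, a minimal adjustment set Z
   satisfying the backdoor criterion is found by d-separation in the graph
   with X's outgoing edges removed (Z contains no descendant of X and
   blocks every path into X).
3. **Estimation and refutation.** The standardized total effect (SD per
   SD) is the X coefficient of OLS Y ~ X + Z, with t-based 95% CI and
   p-value; each estimate is re-computed after appending an independent
   standard-normal "confounder" to Z — a change near 0 indicates an
   estimate robust to this perturbation.

Because the original field data are not public, the package ships a
synthetic twin: `sem_table1()` is a linear-Gaussian structural equation
model over the study's 14 variables whose edge weights are the published
significant effect sizes, with binary factors at their printed prevalences
and raw slider scales matching the published moments.  A per-second signal
generator and feature extractors (steering/braking ratios, sudden events
per hour, flow) cover the sensor-to-table step.

## Worked example

```r
library(tripcausal)

spec  <- sem_table1()                       # ground-truth SEM, 15 edges
trips <- simulate_trips(spec, n = 1638, seed = 1)
dag   <- causal_dag(spec$W, categories = spec$categories)

minimal_backdoor_set(dag, "speed", "after_arousal")
#> adjustment set for speed -> after_arousal: {before_arousal} [minimal]

estimate_effect(trips, "speed", "after_arousal",
                adjust = minimal_backdoor_set(dag, "speed", "after_arousal"))
#>   source        target         ce     ci_low    ci_high      p_value
#> 1  speed after_arousal -0.1866201 -0.2129593 -0.1602809 1.383178e-41
```

The unadjusted regression of after-arousal on speed is biased away from
the true −0.17 because pre-drive arousal lowers speed *and* raises
post-drive arousal; adjusting for the minimal backdoor set
`{before_arousal}` recovers it (−0.187 ± 0.026 at n = 1638 in this
draw).

The full pipeline — simulate (or load), standardize, learn the DAG under
the temporal mask, estimate every edge with its minimal backdoor set, and
run the robustness test — is one call:

```r
res <- run_pipeline(list(
  input = list(synthetic = list(preset = "table1", n = 1638)),
  seed = 1))
res$effects[, c("source", "target", "ce", "ci_low", "ci_high",
                "adjustment_set", "robustness_delta")]
#>           source        target    ce ci_low ci_high adjustment_set robustness_delta
#> 1 before_arousal after_arousal 0.798  0.769   0.828                        4.68e-05
#> 2 before_valence after_valence 0.907  0.887   0.928                       -5.21e-05
```

At n = 1638 with the default pruning threshold ω = 0.3, structure
learning on standardized data keeps the two strong affect-carryover
edges; the `robustness_delta` column shows the mean change of each
estimate over 20 added random confounders (≈ 10⁻⁵ here, i.e. robust).
`run_pipeline(config, out_dir = ...)` additionally writes the DAG as
edge-list CSV/GraphML/DOT, the effect table as CSV, the standardization
sidecar as JSON, and a run log; the same config and seed reproduce all
artifacts byte for byte.  A thin command-line wrapper with subcommands
(`simulate`, `features`, `learn`, `estimate`, `refute`, `all`) is in
`inst/cli/tripcausal.R`.

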