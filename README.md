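# lbgwin

Can a latitudinal biodiversity gradient (LBG) of known shape survive the
fossil record's sampling window?

Deep-time studies of the LBG — the decline of richness from tropics to
poles — rest on fossil collections whose geographic coverage is tiny
(well under 2% of the shallow-marine shelf in any stage) and heavily
skewed toward 30–45° N. `lbgwin` is a simulation framework for measuring
what that does to the signal. It simulates shallow-marine virtual
species whose richness follows a *known* gradient — flat, unimodal
(tropical peak), or bimodal (temperate peaks) — on stage-level 1° × 1°
palaeogeographies spanning the 56 stages from the Asselian (298.9 Ma) to
the Piacenzian (2.58 Ma); filters the occurrences through a per-stage
spatial sampling window (cells containing at least one fossil
collection, real or synthetic); and quantifies how recognisable the
original gradient remains, with and without rarefaction.

## The model in brief

* **Placement.** Species *s* gets an occurrence count from a truncated
  geometric distribution on 1–300 (pmf ∝ e^(−λ(k−1)), λ = 0.05) and a
  log-uniform range extent. Its seed cell is drawn from a probability
  grid over the shallow-marine mask with weight w(φ)·cos φ at latitude
  φ, where w encodes the LBG type (flat: w = 1; unimodal:
  w = e^(−φ²/2σ²), σ = 20°; bimodal: w = e^(−(|φ|−45°)²/2·10°²)); its
  occurrences are drawn from a distance-decay grid
  (weight e^(−3d/range), truncated at the range) around the seed cell.
* **Sampling metrics.** Spatial sampling coverage
  SSC = 100 · sampled/available cells, and summed minimum-spanning-tree
  (MST) length over sampled cell centroids (great-circle, haversine on
  a 6371 km sphere), globally and in twelve 15° palaeolatitudinal bins.
* **Curves.** Distinct-species richness per 15° bin; optional classical
  rarefaction (quota 50, 1000 bootstraps; sub-quota bins are missing,
  with an exact hypergeometric oracle `expected_rarefied_richness()`);
  all curves normalised to proportional form (bin ÷ bin sum).
* **Comparison.** Total displacement D = Σⱼ |c1ⱼ − c2ⱼ| ∈ [0, 2] over
  bins (0 identical, 2 disjoint), per-bin residuals, Pearson's r,
  two-sample Kolmogorov–Smirnov tests, peak bin/zone detection
  (tropics/temperate/polar), richness-versus-sampling R², and Wilcoxon
  rank-sum contrasts between per-stage score series.

See `vignette("lbg-detectability")` for the full model description,
parameter table, and design rationale.

## Worked example

Three Jurassic–Palaeogene stages, unimodal versus bimodal gradients, 200
species × 10 replicates, synthetic windows at 0.7% global SSC skewed
toward 37.5° N with 40% of bins unsampled:

```r
library(lbgwin)
cfg <- experiment_config(
  stages = c("Hettangian", "Aptian", "Chattian"),
  lbg_types = c("unimodal", "bimodal"),
  n_species = 200, n_replicates = 10, do_rarefaction = FALSE,
  window = list(source = "synthetic", target_ssc = 0.7,
                mu = 37.5, sigma = 15, p_zero_bin = 0.4),
  seed = 42)
res <- run_experiment(cfg)
subset(res$sampling, scope == "global")
#>    stage_name  scope ssc_percent   mst_km n_sampled n_available
#> 1  Hettangian global   0.7064967 33012.39        46        6511
#> 14     Aptian global   0.7015032 33502.00        49        6985
#> 27   Chattian global   0.7036944 34650.00        56        7958
```

Each stage's shelf has ~6500–8000 shallow cells, of which only ~50 are
"sampled" (0.70% coverage, matching the target by construction), spread
over ~33 000 km of minimum spanning tree. How distinguishable are the
two gradients before and after looking through that window?

```r
summarize_results(res)$displacement
#>                      pair_label    mean_D       sd_D n
#> 1  bimodal:simulated_vs_sampled 0.9988480 0.23824749 3
#> 2   sampled:unimodal_vs_bimodal 0.7907668 0.24336341 3
#> 3 simulated:unimodal_vs_bimodal 0.8504307 0.03284186 3
#> 4 unimodal:simulated_vs_bimodal 1.3311237 0.14254202 3
```

The displacement between the *true* unimodal and bimodal curves is
steady (D ≈ 0.85 ± 0.03): the types are genuinely different. After
sampling, each type is far from its own truth (simulated-vs-sampled
D ≈ 1.0–1.33), and in two of three stages the *sampled* unimodal and
bimodal curves are more similar to each other (D ≈ 0.65) than the true
curves ever are — the gradients converge on the sampling window.
Peak reports tell the same story: every simulated unimodal peak sits in
the tropics (`0_15N`), but every sampled unimodal peak is displaced
poleward (`15_30N`/`30_45N`), toward the oversampled band. At the scale
of the shipped acceptance checks (40 stages), that convergence is
statistically unambiguous (rank-sum p < 0.01) and sampled unimodal
peaks drift toward 30–45° N in 75% of stages.

Real collection data drop in by replacing the window block:
`window = list(source = "collections", collections_path = "pbdb.csv")`
with PBDB API column names (`collection_no`, `paleolat`, `paleolng`,
`max_ma`, `min_ma`).

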