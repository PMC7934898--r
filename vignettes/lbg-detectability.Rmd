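---
title: "Simulating latitudinal biodiversity gradients through the fossil sampling window"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating latitudinal biodiversity gradients through the fossil sampling window}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbgwin)
```

## The question

The latitudinal biodiversity gradient (LBG) — the decline of species
richness from the tropics toward the poles — is the dominant spatial
pattern of the modern biosphere, but fossil data suggest it has not
always had its modern unimodal shape: flat and bimodal (temperate-peaked)
gradients have been reported for various intervals of the last 300 Myr.
Those reconstructions rest on fossil collections whose geographic spread
is extremely uneven. `lbgwin` asks a simple operational question: if the
true gradient were flat, unimodal, or bimodal, and the only places we
could observe it were the 1° × 1° cells that actually contain fossil
collections, would we still recognise it?

The package answers by simulation. Virtual species with known richness
gradients are scattered across stage-level shallow-marine
palaeogeographies; the resulting occurrence tables are filtered through a
per-stage *sampling window* (the set of sampled cells); and simulated,
sampled, and sampling-standardized latitudinal richness curves are
compared with a battery of statistics. Everything is stage-resolved on
the 56-stage Asselian–Piacenzian scaffold (`build_stage_table()`,
298.9–2.58 Ma, contiguous bounds summing to 296.32 Myr).

## The simulation model

**Geography.** Each stage needs a global 1° elevation grid from which the
shallow-marine domain (elevation in [−200, 0) m, approximating the photic
zone) is extracted. Real stage-level elevation models are typically
proprietary, so the package ships a synthetic generator
(`generate_synthetic_dem()`): a few elliptical continental plates with
land cores, shelf aprons grading linearly from shoreline to 200 m depth,
and −4000 m ocean elsewhere; plate centres drift a fixed angular step per
stage (default 0.7°), so consecutive stages share most of their land
(Jaccard similarity of land cells ≥ 0.8 in tests). The generator is
first-class, deterministic under its seed, and any 1° grid in the
supported ASCII raster dialect can replace it. Grid cells are 1° × 1°,
centred at half-degrees; a point maps to its cell by flooring
(lat + 90) and (lon + 180). Cell registration is a package convention:
nothing in the scientific design depends on corner versus centre
registration, but one convention had to be fixed for determinism.

**Species.** Each virtual species receives (i) an occurrence count drawn
from a truncated geometric distribution on 1–300 — the discrete form of
an exponential decay of occurrence frequency, rate 0.05 per occurrence by
default — and (ii) a range extent drawn log-uniformly between 100 and
15 000 km. Both distributions are configurable (`decay_params()`); the
defaults were chosen once to span the orders of magnitude observed in
modern marine invertebrate range-size compilations, and are deliberately
generic rather than fitted to any particular empirical group.

**Placement.** An LBG type is imposed through a weighted probability grid
over the shallow mask (`build_probability_grid()`): the weight of a cell
at latitude φ is w(φ)·cos(φ), where w is 1 (flat),
exp(−φ²/2σ²) with σ = 20° (unimodal), or exp(−(|φ|−45°)²/200) (bimodal,
σ = 10°). The cos(φ) factor makes placement uniform per unit *area*
rather than per cell; it can be disabled, but area-true placement is the
conservative default on a longitude–latitude grid. Each species draws an
initial cell from this grid, then its occurrences are drawn (with
replacement) from a distance-decay grid centred there: weight
exp(−3d/range) for great-circle distance d, truncated at the range
extent, which puts ~95% of the mass well inside the range and enforces a
hard cap. Because occurrences are cell-level and richness is a
distinct-species count, repeat draws of one cell are harmless — they
mimic repeated collection of a common species. The steepness of realised
gradients is also shaped by available shelf area per latitude band (a
species–area effect): a band with twice the shallow cells at equal weight
ends up substantially richer, which the test suite verifies directly.

**Sampling window.** From real data, a cell is "sampled" if at least one
collection with palaeocoordinates falls in it
(`read_collections()`, `assign_to_stage()`, `rasterize_window()`);
windows are clipped to the shallow mask, never snapped to it. Collections
spanning several stages are assigned by age midpoint by default (each
collection lands in exactly one stage); a strict-containment rule is
available. The synthetic generator (`generate_synthetic_window()`)
reproduces the three features of the real record that drive the study:
sub-2% global spatial sampling coverage (default 0.7%, drawn without
replacement so coverage is exact), a Gaussian latitudinal skew centred on
37.5° N (σ = 15°), and a 40% chance of zeroing each 15° bin outright.

**Metrics and curves.** Spatial sampling coverage (SSC) is the percentage
of sampled cells among available (shallow-marine) cells; bins with no
available cells are *undefined*, not 0%. Sampling extent is the summed
minimum-spanning-tree length over sampled cell centroids under
great-circle distances (haversine, radius 6371 km; 1° at the equator =
111.19 km), computed globally and per bin — per-bin trees never cross bin
boundaries. Richness curves count distinct species per 15° bin; classical
rarefaction standardises each bin to a 50-occurrence quota with 1000
bootstrap draws by default, leaving sub-quota bins missing (grey tiles)
rather than estimating at a reduced quota, so values stay comparable
across bins. All curves are normalised to proportional form (bin ÷ bin
sum) before comparison, because the object of interest is the *shape* of
the gradient, not absolute richness.

**Comparison statistics.** For a curve pair: per-bin residuals
(test − reference); total displacement D = Σ|difference| over bins,
ranging 0 (identical) to 2 (disjoint support); Pearson's r with its
two-sided p; a two-sample Kolmogorov–Smirnov test on the per-bin values;
and peak bin/zone reports (tropics |φ| < 30°, temperate 30–60°, polar
≥ 60°, hemispheres merged for zone matching). When a curve has missing
bins, pairwise statistics restrict to jointly non-missing bins, and for D
both curves are re-normalised over that joint support so the [0, 2] range
is preserved — the one place where a policy for missing data had to be
invented, chosen to keep the metric's documented bounds meaningful.
Detection ties are broken toward the tropics (and North before South),
always with an explicit tie flag. Score series across stages are
contrasted with two-sided Wilcoxon rank-sum tests, and richness is
regressed on SSC/MST via squared Pearson correlations (`r_squared()`).
KS inputs are the per-bin curve values (n ≤ 12 per sample); the procedure
is deliberately simple and its small n is reflected in the asymptotic
p-values.

## The pipeline

`experiment_config()` + `run_experiment()` orchestrate
geography → simulation → windowing → metrics → curves → comparisons from
one validated config (or YAML file). Replicate-level raw curves are
averaged first and the mean curve is then normalised (per-replicate
normalisation is a config switch); rarefied curves are means of per-bin
bootstrap means, averaged across replicates. Every stage × type cell is
seeded as `derive_seed(master, stage_index, type_index)`, with replicate
r re-seeded from the cell seed, so any subset of an experiment reproduces
bit-identically; the scheme is recorded in the run manifest together with
a config hash, and occurrence tables are cached per cell under the hash
so interrupted runs resume without recomputation. A failing cell is
logged in the manifest and does not abort the rest. `summarize_results()`
emits the four headline tables: displacement series (mean, σ),
KS-significant stage fractions, peak bin/zone recovery percentages, and
richness-versus-sampling R².

## Default parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_species` | 1000 | species per replicate |
| `n_replicates` | 100 | replicates per stage × type |
| `quota` | 50 occurrences | rarefaction quota per bin |
| `n_boot` | 1000 | bootstrap draws per bin |
| `sigma_uni` | 20° | width of the tropical peak |
| `mu_bi`, `sigma_bi` | 45°, 10° | position/width of temperate peaks |
| `rate` | 0.05 | occurrence-count decay per occurrence |
| `range_min`–`range_max` | 100–15 000 km | log-uniform range extents |
| `target_ssc` | 0.7% | synthetic window global coverage |
| `mu`, `sigma` (window) | 37.5° N, 15° | latitudinal sampling skew |
| `p_zero_bin` | 0.4 | chance a 15° bin is wholly unsampled |

The full defaults are desk-unfriendly by design (they describe the study
conditions); the test suite and examples run reduced sizes. The shipped
checks use: 2 stages × 3 types × 3 replicates × 100 species for the
identity-window equivalence; and 40 synthetic stages × 2 types × 10
replicates × 200 species for the detectability contrast. Forty stages
(the contrast needs at least ~20) gives the rank-sum test reasonable
power at this reduced species count while keeping the run inside a few
minutes.

## What the synthetic data do and do not show

The synthetic geography reproduces the *structural* features the method
depends on — a shallow shelf fringing drifting continents, latitudinally
uneven shelf area, windows that are tiny, northern-skewed and full of
holes — but not the actual continental configurations of the
Permian–Neogene, nor epicontinental seaways, nor the empirical range-size
and occurrence-frequency distributions of any real clade. Consequently,
passing tests demonstrate that the *machinery* behaves as specified and
that the qualitative detectability result (unimodal and bimodal gradients
converge after realistic sampling; sampled peaks drift toward the
oversampled band) emerges under the stated sampling conditions. They do
not reproduce the magnitudes any particular real-data analysis reports,
which depend on proprietary elevation models and a specific collection
snapshot.

## Numerical choices and degenerate inputs

* Shoreline cells (elevation exactly 0) are land; −200 m exactly is
  shallow. A closed–open interval avoids double counting at the coast.
* Curves that are all-zero or all-missing normalise to all-missing with
  a warning; comparisons on them return `NA` rather than crashing.
* Zero-variance inputs to correlations are flagged `defined = FALSE`
  instead of erroring, since flat curves are a legitimate treatment.
* MST node order is fixed lexicographically so equal-weight edge ties
  resolve deterministically.
* All internal seeding saves and restores the caller's RNG state.

## Limitations

Species are placed independently (no climate, dispersal, or interaction
structure), stages are simulated independently (no range-through), and
the sampling rule is the optimistic "all occurrences in a sampled cell
are recovered". Each of these simplifications biases the framework
*toward* detectability, so detection failures under the simulated windows
are conservative findings. Rarefaction is the only standardisation
implemented; coverage-based or extrapolation estimators are out of scope,
and no multiple-testing correction is applied across stages.
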