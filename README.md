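# telemsoc

Telemetry-based fission–fusion staging and social network analysis for
multilevel animal societies.

## The problem

Multilevel societies — nested social systems in which one-male units
aggregate into breeding bands, bands associate with all-male units and
solitary males to form herds, and herds seasonally fuse into a troop — are
almost impossible to study by direct observation: the components range over
tens of square kilometres of rugged terrain and cannot be followed
simultaneously. A practical design is to put a GPS collar on one animal in
each *social component* and analyse the joint movement of those components.
`telemsoc` implements that analysis chain for behavioural ecologists:

1. **Preprocessing** of collar fixes on a diurnal sampling grid (e.g. every
   2 h from 05:00 to 19:00): removal of low-accuracy fixes (dilution of
   precision, DOP ≥ 8), reconstruction of missing fixes by piecewise cubic
   splines on the true timestamps, and smoothing by a centred 15-fix moving
   average.
2. **Fission–fusion staging** via the *spatial affinity coefficient* (SAC).
   At time segment *i*, with per-dimension population variances of the *n*
   component positions σ²(lon), σ²(lat) (degrees²), the spread modulus is

   A_i = sqrt(σ²_lon + σ²_lat),

   i.e. the two-dimensional s.d. of the component positions, and
   SAC_i = (A_i / A_max)² standardizes it into [0, 1] (quadratic min–max;
   linear available). Thresholds come from a communication geometry: place
   the n components at the vertices of an isogon (equilateral polygon) whose
   side is the effective communication distance d; the circumcircle radius
   d / (2·sin(π/n)) is the spread at which the formation sits exactly at
   communication range. Standardizing that radius for side d gives
   SAC^fusion, for side 2d gives SAC^fission (ratio exactly 4 under the
   quadratic map). Runs of ≥ 3 segments below/above the thresholds are
   fusion/fission stages; intermediate spans after a fission are *reform*,
   after a fusion *separation*.
3. **Association networks**: per-segment nearest neighbours, half-weight
   index HWI = X / (X + Y_ij + (Y_i + Y_j)/2) per dyad (X mutual-neighbour
   counts), average-linkage dendrogram on 1 − HWI cut at maximum weighted
   Newman modularity (the recommended herd cutoff), lagged vs null
   association rates with constant / offset-exponential decay fits, and
   principal coordinates embedding of d_ij = 1/√HWI.
4. **Home ranges**: bivariate Gaussian kernel utilization distributions on a
   local planar frame, smallest-area isopleths (default 95%), areas in
   hectares and pairwise overlap percentages (intersection-over-union or
   fraction-of-first).
5. **Synthetic telemetry**: a biased correlated random walk generator with a
   scheduled stage sequence, planted two-herd structure and collar-like
   degradation (DOP, jitter, missingness), giving every downstream stage a
   ground truth.

## Worked example

```r
library(telemsoc)

cfg <- synth_config(n_days = 60, seed = 42)   # 5 components, 8 fixes/day
gen <- generate_trackset(cfg)                 # clean tracks + ground truth
raw <- degrade(gen$trackset, cfg)             # collar-like fix table
ts  <- preprocess_trackset(trackset(raw, cfg$grid))

sac <- sac_series(ts)
th  <- sac_thresholds(attr(sac, "standardizer"), d = 513.12, n = 5)
th
#> threshold_set: d=513.12 m, n=5 -> SAC_fusion=0.1590, SAC_fission=0.6360 (persistence 3)

classify_stages(sac$sac, th, slots = sac$slot)
#> stage_segmentation: 24 segments over 479 slots
#>   fission: 19.4%
#>   reform: 20.5%
#>   fusion: 28.2%
#>   separation: 31.9%

am <- hwi_matrix(nearest_neighbours(ts))
cluster_dendrogram(am)
#> herd_dendrogram: 5 components, max modularity 0.3916 at k=2 (cut height 0.907)
#> membership: C01=1, C02=1, C03=1, C04=2, C05=2
```

The thresholds are the standardized circumcircle radii for isogon sides
513.12 m and 1026.24 m. The segmentation recovers the generator's scheduled
stage mix (at 60 days the 15-fix smoothing window blurs stage boundaries
more than at full study length; at 291 days recovery is within ~2 percentage
points). The dendrogram cut at maximum modularity recovers the planted
two-herd structure (components 1–3 vs 4–5).

The same chain is available as one call with a run directory of delimited
outputs and a JSON manifest:

```r
run_pipeline(run_config(synth = synth_config(seed = 1), seed = 1), "run1")
```

or from the shell via `inst/cli/telemsoc.R`:

```sh
Rscript inst/cli/telemsoc.R run-all --config run.yml --out run1 --seed 1
```

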