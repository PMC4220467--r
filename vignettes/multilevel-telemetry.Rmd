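---
title: "Staging fission–fusion dynamics and estimating multilevel social structure from collar telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging fission-fusion dynamics and estimating multilevel social structure from collar telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telemsoc)
```

`telemsoc` analyses the joint movement of the *social components* of a
multilevel animal society — breeding bands, all-male bands or units, and
solitary males — each represented by one GPS-collared animal. This vignette
is the package's account of the models it implements, the tunable
parameters, the synthetic data used for validation, and the numerical and
design decisions behind them.

## The sampling model

Collars record on a diurnal grid: `slots_per_day` fixes at fixed hours
(default 8, every 2 h from 05:00 to 19:00 local time). The 10-hour overnight
span is a design feature of the grid, not missing data, and all lag-based
quantities count lags in grid slots (2 h). Two imperfections are modelled
explicitly:

* fixes with high **dilution of precision** (DOP) are unreliable and are
  removed at a strict threshold (`dop >= 8` by default);
* weather or canopy occasionally prevents a fix entirely.

Both produce gaps, reconstructed by a piecewise cubic spline fitted per
coordinate against the *true* timestamps (so the overnight span enters at
its real length) and evaluated only at empty grid slots. Leading and
trailing gaps are not extrapolated, and gaps whose bracketing fixes are more
than one calendar day apart are left empty and flagged — a spline has no
information at that range and would oscillate. Tracks are then smoothed with
a centred moving average of 15 fixes (the window shrinks symmetrically near
the series ends, so constant and interior-linear tracks are invariant) and
finally aligned: only slots at which *every* component is located are kept.
The order filter → interpolate → smooth → align is fixed and recorded in the
trackset log.

The 15-fix window is a deliberate interpretation: with an averaging window
specified only as "15 points", a centred window truncated symmetrically at
the ends is the simplest reading that is unbiased for linear motion. Its
side effect matters for staging: a step change in dispersion becomes a
~15-slot ramp, so stage boundaries blur by roughly ±7 slots (see below).

## The spatial affinity coefficient

At segment *i* the positions of the *n* components are summarised by the
per-dimension **population** variances (divide by *n*, not *n* − 1) of
longitude and latitude in degrees, and the spread modulus

$$A_i = \sqrt{\sigma^2_{lon,i} + \sigma^2_{lat,i}},$$

the two-dimensional s.d. of the component positions. Population variance is
a substantive choice: it makes the spread of *n* points at the vertices of a
regular polygon equal the circumcircle radius exactly, which is what lets a
communication geometry be translated into a spread threshold. Degrees are
treated isotropically with the constant `t = r·2π/360` km/degree
(`r = 6378.137` km); an optional cos-latitude ("latitude-corrected") planar
projection exists for the home-range module, where metric areas matter, but
the affinity statistic follows the constant-`t` convention so that a
distance *d* in metres is always `d / 1000t` degrees regardless of
direction. Coordinates are centred before squaring: positions are O(100)
degrees while spreads are O(0.01), and the naive `E[x²] − E[x]²` form loses
about twelve significant digits.

`standardize_sac()` maps A into [0, 1]. The default is the **quadratic
min–max** `SAC = (A/A_max)²`, calibrated on the analysed series; linear
min–max is selectable. The quadratic default was chosen because the two
stage thresholds in the reference analysis of this method (0.1139 and
0.4571, for communication distances d and 2d) stand in ratio ≈ 4 — the
square of the 2× geometric ratio — which a linear map cannot produce.
Whether calibration should be global over the study or windowed is genuinely
open; global is the default because staging compares segments *across* the
whole study, and a windowed option would make SAC values incomparable
between windows.

### Thresholds from communication geometry

Components are assumed able to coordinate within an effective communication
distance *d* (default 513.12 m, a field estimate of the maximum inter-unit
distance at which a band still behaves as one formation). Placing the *n*
components at the vertices of an isogon with side *d* gives circumradius
`d/(2 sin(π/n))`; standardizing that radius yields `SAC_fusion`, and the
radius for side 2*d* (beyond visual/vocal contact) yields `SAC_fission`.
Under the quadratic standardizer the two are in exact ratio 4 before
clipping; a threshold radius beyond the calibration maximum clips to 1 with
a warning. Explicit numeric overrides (e.g. reusing a published pair such as
0.1139/0.4571) bypass the derivation, because the calibration constant
behind published values is generally unrecoverable.

### The four-stage state machine

With persistence *p* (default 3 consecutive segments; the verbal definition
"more than three time segments (≥ 4 h)" is internally inconsistent at 2-h
sampling, and ≥ 3 segments = 6 h is the reading adopted, configurable):

* a run of ≥ *p* segments with `SAC ≤ SAC_fusion` is a **fusion** stage;
* a run of ≥ *p* segments with `SAC ≥ SAC_fission` is a **fission** stage
  (both comparisons inclusive);
* shorter excursions do not interrupt a surrounding stage — two same-type
  cores separated by fewer than *p* other segments merge across the
  excursion;
* remaining segments take the label implied by their neighbours: after a
  fission and before the next fusion they are **reform**; after a fusion
  until the next fission they are **separation**. Leading segments are
  labelled by the next event; a series with no threshold crossing at all is
  labelled separation with a warning (reform and separation are defined only
  relative to neighbouring events, so some convention is required; the
  next-event rule keeps labels consistent with the eventual transition).

The classifier is tested for exact equivalence against an independent
sliding-window reference on all 3^8 coarse sequences and tens of thousands
of random real-valued series.

## Association analysis

Association is sampled by **mutual nearest neighbourhood** per 2-h segment:
for each component, the other component at minimum great-circle (haversine,
r = 6378.137 km) distance, ties broken to the smallest identifier and
flagged. For a dyad (i, j), X counts segments where each is the other's
nearest neighbour, Y_i / Y_j one-way relations, Y_ij segments where both
have other neighbours; the **half-weight index** is
`HWI = X / (X + Y_ij + (Y_i + Y_j)/2)`. The half-weight form (one-way
relations at half weight in the denominator) is the canonical choice in the
SOCPROG tradition this analysis follows; the package treats it as a design
decision since association indices differ mainly in how they discount
asymmetric sampling.

* **Herd cutoff**: average-linkage agglomeration on 1 − HWI; every cut of
  the tree is scored by weighted Newman modularity with HWI edge weights
  (computed only at partitions the dendrogram realises, not by free
  optimisation), and the recommended cutoff is the cut of maximum
  modularity. Knot counts (cumulative bifurcations by association distance)
  are reported alongside. A caveat discovered and tested during development:
  a planted block of size 1 is undetectable by modularity (a singleton has
  no within-block edges and the single-cluster partition scores 0 ≥ its
  modularity), so "herds" of one component will merge into their nearest
  cluster.
* **Lagged association rate**: `g(τ) = Σ a(t)·a(t+τ) / Σ a(t)·o(t+τ)`
  pooled over dyads and slot pairs, with the **null rate** the pooled mean
  association probability. Two decay models are fitted by least squares —
  constant companionship `g = a` and decaying acquaintance
  `g = a·e^(−bτ) + c` — and compared by AICc.
* **Principal coordinates**: classical metric scaling of
  `d_ij = 1/√HWI_ij`; dyads with HWI = 0 receive a ceiling dissimilarity
  (default 10× the largest finite value, flagged), and negative eigenvalues
  are truncated to zero and reported.

## Home ranges

Each component's fixes are projected to a local planar km frame
(equirectangular at a reference latitude — per component by default, or a
shared reference when ranges are to be overlaid) and smoothed with a
bivariate Gaussian kernel (`MASS::kde2d` semantics wrapped so that
`bandwidth` is the kernel s.d. in km). The default bandwidth is
`stats::bw.nrd0` per dimension — Silverman's rule of thumb, R's own
reference default. The grid extends three bandwidths beyond the data hull
and the density is renormalised to integrate to 1. The *q*-isopleth
(default 0.95, the field standard; the choice is configuration, not
doctrine) is the smallest-area region of total probability ≥ *q*, found by
admitting cells in decreasing density order; areas are reported in hectares.
Overlaps are computed on a shared fine raster (the standard practice for
kernel ranges) in two modes: symmetric intersection-over-union, and
fraction-of-first for directional statements; the mode is recorded in the
output because published "X overlapped Y by …%" phrasings are ambiguous.
Reference-rule kernels mildly overestimate areas (the estimated density is
the truth convolved with the kernel, inflating variance by the squared
bandwidth — about 3% at 5,000 fixes); tests budget for this.

## The synthetic telemetry generator

The generator exists so that every stage of the chain can be validated
against known truth; it emulates the study design, not behavioural detail
(no foraging, dominance or transfer events). Defaults are the study
conditions: 5 components, 291 days × 8 fixes/day, stage composition
20.9/24.7/18.4/36.0% of the period arranged in six
fission → reform → fusion → separation cycles, 2% high-DOP fixes, 2.7%
missing fixes.

Movement is a biased correlated random walk: a shared formation centroid
follows a correlated random walk (velocity AR(1) coefficient 0.7, step scale
0.2 km/slot, weak home pull), and each component's offset from the centroid
relaxes (rate 0.5/slot, Gaussian noise s.d. 0.05 km per coordinate) toward a
stage-dependent target. Targets are a fixed *formation shape* scaled by a
stage radius. Two shapes with unit spread modulus are planted:

* a **clustered shape** for fission, reform and separation — each herd's
  members on a small ring around its herd centre (components 1–3 vs 4–5 by
  default, mirroring a herd of band + satellite units vs a neighbouring
  pair), centres balanced so the configuration mean is zero. Cross-herd
  gaps exceed within-herd spacing by ~80%, so mutual nearest neighbours
  stay within herds except under extreme noise;
* a **regular n-gon** during fusion, where the merged troop intermingles
  and herd identity carries no spatial signal. For the polygon the spread
  modulus equals the circumradius *and* the maximum centroid-to-component
  distance, so the fusion radius bounds every component's offset exactly.

Because both shapes have unit spread, the realized spread statistic equals
the stage radius exactly in the noise-free limit. The default radii —
fusion 0.25 km, intermediate 0.62 km, fission 1.10 km — were chosen once,
before any testing, to straddle the communication-geometry thresholds for
the default parameters (A^fusion = 0.436 km and A^fission = 0.873 km for
n = 5, d = 513.12 m) symmetrically: the 15-fix smoothing ramp between two
stage plateaus then crosses each threshold at the scheduled boundary with
little bias. Residual bias remains — the cluster↔polygon rearrangement at
fusion boundaries takes a few slots of travel, and recovered fusion time
runs ~2 percentage points high at study scale — which is why the recovery
tests assert ±5 points, not exactness. Within-day movement autocorrelation
is exposed as `heading_persistence` rather than fixed: the study design
does not determine it, and it does not affect the staging mathematics, only
the realism of the centroid path.

Degradation draws DOP from a log-normal capped below 8, reassigns a
configured fraction to DOP ∈ [8, 20] with larger position jitter (50 m vs
10 m s.d.), and deletes a configured fraction of fixes. All randomness
derives from the single configured seed (degradation uses a fixed offset of
it), so identical configurations are bit-identical — the property the
pipeline's manifest checksums rely on.

**What passing tests do and do not show.** The generator realises the
*spread regimes* and a stationary two-block association structure; it does
not model habitat, tortuosity, fix-rate heterogeneity, collar failure
bursts, or gradual social change. Recovery of stage fractions and herd
structure on these data validates the estimators' mathematics and the
pipeline's plumbing; it does not certify performance on field data whose
dispersion dynamics violate the threshold geometry (e.g. communication
distances that drift seasonally).

## Numerical choices and degenerate inputs

* Spread variances are centred before squaring (twelve digits of
  cancellation otherwise); `A = 0` only when all components coincide.
* A constant-zero spread series cannot be standardized (rejected).
* Nearest-neighbour ties use a relative tolerance of 1e−9 on distance;
  collar coordinates carry no more precision.
* The exponential decay fit starts from a log-linear regression slope and
  uses Levenberg–Marquardt; non-convergence is reported per model while the
  constant model is kept.
* Dendrogram cut heights at k clusters are midpoints between consecutive
  merge heights; the modularity argmax breaks ties toward fewer clusters.
* `cmdscale` embeddings with fewer positive eigenvalues than requested
  dimensions are returned at the reduced rank with a warning.
* KDE on fewer than 10 fixes, or on identical fixes, is rejected.
* Overlap rasterization uses the UD grid mask directly for kernel ranges
  and an even-odd crossing-number test for explicit polygons (no polygon
  clipping library is required at the accuracy overlap percentages need;
  the raster resolution is configurable).

## Problem sizes used by the test-suite

Unit tests run on 1–60 day tracksets; recovery experiments use the full
291-day study design over 20 seeds; classifier equivalence is exhaustive
over all 3^8 coarse sequences plus 10,000 random series; HWI tallies are
verified exactly on 1,000 random neighbour tables; kernel-range geometry is
checked at 5,000 fixes against the bivariate-normal closed form. These sizes
were chosen as the smallest that exercise each property convincingly.

## Known limitations

* Staging depends on the standardizer calibration: appending data changes
  `A_max`, hence SAC values and (derived) thresholds. Use explicit
  threshold overrides for rolling analyses.
* The SAC is a single global dispersion number; it cannot tell *which*
  components drove a fission, and the package deliberately does not locate
  merge/split events in space.
* Modularity cannot isolate single-component herds (see above); the PCoA
  and the dyad-level HWI table are the right tools there.
* Kernel ranges use independent-fix estimators; strongly autocorrelated
  fixes make them optimistic, and autocorrelation-corrected estimators are
  out of scope.
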