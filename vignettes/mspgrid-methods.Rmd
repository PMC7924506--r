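---
title: "mspgrid: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mspgrid: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mspgrid)
```

# Scope

`mspgrid` computes two grid-based decision-support products for maritime
spatial planning: Maritime Use Conflict (MUC) maps, which score the spatial
overlap of human uses of the sea, and Cumulative Effects Assessment (CEA)
maps, which accumulate pressure effects on environmental receptors. This
vignette records the modelling assumptions, the defaults and their
rationale, the numerical conventions, and the limitations a user should
know before trusting a map.

# The analysis grid

All computation happens on a rectified grid: a regular raster over a
rectangular extent in a projected, meter-unit coordinate reference system.
The shape is `ceil(extent / resolution)` in each axis; the pixel convention
is top-left origin, pixel-is-area, half-open cell intervals. Cell
membership of a polygon is decided by the cell *center* (even-odd rule) —
a deterministic rule whose bias shrinks with resolution and which keeps
rasterization consistent when the same footprint is burned at different
resolutions. Lines and points burn every cell they touch; line traversal is
detected by sampling each segment at one fifth of the cell size, which can
in principle miss a corner clip shorter than that step — at the 500 m
working resolution this is a sub-100 m sliver.

No geodesy engine is bundled: the crs is carried as an opaque identifier,
screened against well-known geographic codes (a degree-unit grid would make
every distance parameter meaningless), and vector inputs must already be in
the grid's crs.

Nodata is stored as `NA`. Inside convolution and sums nodata counts as
zero mass; in maxima and statistics it is excluded; `log_scale` and
`reclassify` propagate it unchanged. Normalizing an all-zero layer returns
it unchanged rather than erroring: zero layers legitimately arise from
empty use subsets, and erroring would make "subset, then run" fragile.

# MUC

Each use carries four COEXIST attributes: vertical domain(s) (non-empty
subset of surface / water column / seabed), spatial domain (local /
large), temporal domain (seasonal / year-round) and mobility (mobile /
fixed). The pairwise potential conflict score is

    score(a, b) = gate(a, b) * (R_mob + R_spa + R_tmp)

with a vertical-overlap gate (disjoint vertical domains cannot physically
interfere, hence score 0) and three additive components, each a symmetric
2×2 table with entries in {0, 1, 2}:
fixed+fixed = 2, fixed+mobile = 1, mobile+mobile = 0, and analogously
large/local and year-round/seasonal. The attainable total therefore spans
0–6, and the qualitative logic is that persistent, spatially extensive,
immobile co-located uses conflict most. These default tables are a
reconstruction of that qualitative logic, not a published calibration; the
rule set is an explicit configuration object (`default_ruleset()`) so a
calibrated table can be substituted entry by entry, and studies comparing
absolute scores across rule sets should say which tables they used.

Presence is intensity strictly greater than zero by default
(`presence_layers(threshold = 0)`): the model consumes presence/absence
semantics, and any positive intensity is evidence of presence. Self-pairs
are excluded and multiple features of one use in a cell count once. The
per-cell accumulation is exact integer arithmetic; the pair-contribution
table is consistent with the map by construction and tested against a naive
cells × pairs loop.

# CEA

Pressure fields are assembled per pressure `p` as

    P_p = norm( Σ_{links u→p} w_u · G_{d_u} * U_u )

* `G_d` is an isotropic Gaussian kernel. The propagation distance `d`
  (meters) is interpreted as the *effective radius*: σ = d/3, so ≈99.7% of
  the kernel mass falls within `d`. The kernel is truncated at 4σ and
  renormalized to unit sum, making smoothing mass-conserving up to boundary
  truncation (verified to 1e-6 relative for interior sources). Convolution
  is separable (two 1-D passes) with zero padding; `d = 0` is the exact
  identity. Convolution is applied before weighting; the two orders are
  mathematically interchangeable (both operators are linear).
* Weights `w ∈ [0, 1]` are *relative* pressure weights; after the weighted
  sum the field is normalized to unit maximum by default, so sensitivities
  remain the only scale carrier. Pass `normalize_pressures = FALSE` to
  `run_cea()` for absolute-intensity studies. One consequence of relative
  normalization worth knowing: removing a *use* from a case study rescales
  the pressure fields it fed, so per-cell CEA values are monotone under
  subsetting of pressures and receptors, but not necessarily under
  subsetting of uses.
* Environmental layers are normalized to `[0, 1]` once, at case-study
  construction; `cea_map()` asserts the range rather than silently
  rescaling, so a unit mistake surfaces as an error instead of a wrong map.

The cumulative score is `Σ_{p,e} P_p · E_e · s(p, e)` with sensitivities
`s ≥ 0`. Every term is kept as a partial-effect layer; the decomposition
`total = Σ partials` holds cellwise to 1e-9 and is tested, as are
linearity in the sensitivities and monotonicity when one sensitivity grows.
"Effects" and "impacts" are treated as one quantity: no separate impact
transformation is applied. Whether pressure intensities should be
log-transformed before combination is study-specific; it is available as a
pre-processing expression (`"log1p(...)"`) rather than hard-coded.

# The expression language

Case-study layers may carry a pre-processing expression — a small,
purely-functional map calculator over named layers: infix `+ - * /`,
comparisons yielding 0/1 mask layers (so masks compose with arithmetic),
and the whitelist `norm`, `log1p`, `gaussian(x, d)`, `rescale(x, lo, hi)`,
`where(cond, a, b)`, `min`, `max`, `sum`, `mean` (the last four cellwise
over their arguments, which is all the "aggregation" the engine exposes).
The grammar is conventional infix precedence with parentheses; it was
chosen as the minimal grammar covering the transformations the models
need. Two deliberate choices:

* **Security.** Evaluation is a tree-walking interpreter; the source text
  is never handed to R's evaluator, and any call outside the whitelist is a
  parse error with a character offset. Case-study bundles from third
  parties therefore cannot execute code.
* **Hyphenated identifiers.** Layer codes may contain hyphens
  (`[A-Za-z_][A-Za-z0-9_-]*`), so `a-b` is one identifier and subtraction
  between named layers must be spaced: `a - b`.

Each whitelisted function is tested for exact agreement with the grid
operator it delegates to, and parse–unparse–parse is a fixed point.

# Statistics and reports

`layer_statistics()` summarizes in-area, non-nodata cells: count, mean,
sample standard deviation, extremes, the 5/25/50/75/95 percentiles and a
histogram whose edges span `[min, max]` exactly (a constant layer yields
one bin; counts always sum to the cell count). Percentiles use linear
interpolation between order statistics (quantile type 7) — fixed and
documented so results are deterministic and testable. Reports never embed
timestamps in data files (only in `run.json`), keeping outputs diffable;
rasters are written with 17 significant digits so a write/read round trip
is bit-exact.

Rasters use the ESRI ASCII grid format: a plain-text, universally readable
raster interchange format whose one limitation — no embedded crs — is
covered by the manifest and run metadata. Reclassification uses
left-closed, right-open intervals `[b_i, b_{i+1})`.

# The synthetic generator

`generate_case_study()` produces structurally valid, fully reproducible
case studies with no external data. Defaults describe the documented study
conditions: a 10 km × 10 km square at 500 m resolution (a typical regional
working resolution, and small enough that every test and example runs in
seconds), three uses, two environmental components, two pressures.
Footprints are unions of random rectangles and disks grown until a target
coverage density (default 0.15 — sparse, as real use footprints are) is
reached; environmental components are Gaussian-smoothed uniform noise
rescaled to `[0, 1]`; attributes are drawn uniformly from their
vocabularies; every use exerts at least one pressure (weights in
`[0.2, 1]`, distances in {0, 1, 2, 5} km) and the sensitivity table covers
the full pressure × component cross with scores in `[0, 3]`. A single
integer seed drives one pseudo-random stream, isolated from the caller's
RNG state, so the same spec always writes byte-identical bundles.

What the generator does *not* emulate: the spatial autocorrelation
structure, class imbalance and coastline geometry of real marine data, or
expert-calibrated weight/sensitivity tables. Passing tests on synthetic
cases therefore demonstrates algorithmic correctness — score accumulation,
propagation, decomposition, round trips — not ecological realism of any
particular map.

# Verification strategy and problem sizes

Every model path is checked against an independent naive oracle: MUC
against a per-cell, per-pair triple loop; CEA against a per-cell
sensitivity-row loop (agreement to 1e-9 on grids up to 10 × 10, up to 5
uses, 3 pressures × 2 envs, across 50 random seeds); rasterization against
a ray-casting containment oracle; percentiles against a sort-based
interpolation formula; the score range against exhaustive enumeration of
all 56 × 56 attribute-profile pairs. Conservation laws (convolution mass,
CEA decomposition, MUC pair totals, histogram counts) and round trips
(bundle save/load, raster reload, seeded regeneration) are asserted
exactly or at the stated tolerances. End-to-end runs use 20 × 20 grids at
500 m — sizes chosen so the full suite exercises every feature in well
under a minute while remaining large enough for footprints, propagation
kernels and masks to interact.

# Known limitations

* No reprojection: all inputs must share the grid's crs.
* Polygon coverage is center-based; fractional cell coverage is not
  computed. At coarse resolutions narrow footprints can vanish — rasterize
  at finer resolution or buffer the geometry upstream.
* The default conflict rule tables are a qualitative reconstruction (see
  above), and the CEA response is linear in pressure, exposure and
  sensitivity — threshold or saturating ecological responses are out of
  scope.
* Gaussian propagation is isotropic and ignores coastlines, bathymetry and
  currents; a pressure can "smooth across" a land mask, which should be
  applied after propagation where that matters.
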