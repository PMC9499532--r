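---
title: "Methods: from luminescence time-lapse images to root trait trajectories"
author: "rhizotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from luminescence time-lapse images to root trait trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rhizotrack quantifies root system architecture (RSA) from day-by-day
luminescence images of plants grown in thin soil-filled rhizotrons
(15 cm wide by 30 cm deep). Roots expressing a luciferase reporter emit
light after luciferin watering; a camera records one 16-bit grayscale frame
per rhizotron per imaging day. The signal is sparse and curvilinear, decays
in older tissue, is interrupted where soil occludes the root, and sits on
speckle noise plus a fixed camera background. This vignette explains each
stage of the pipeline, the parameters that matter, and the design choices
made where more than one implementation was defensible.

Throughout, images use the convention: origin top-left, `x` rightward, `y`
downward, 0-based pixels; gravity points along +y, and a segment's *gravity
angle* is measured from the downward vertical (0° = straight down, 90° =
horizontal).

## The synthetic rhizotron

Every stage is tested against simulated ground truth, so the simulator is
first-class code. `simulate_root_growth()` is a stochastic sampler, not a
mechanistic model: a primary root descends from the sowing position at
`primary_elongation_rate` (default 1.5 cm/day), and first-order laterals
initiate along it as a Poisson process (`lateral_initiation_rate`, default
0.5 laterals per day per cm of branching-competent length, excluding a 1 cm
apical zone). Each root holds a gravity set-point: 0° for the primary,
`lateral_gravity_setpoint` (default 60°, signed by a random left/right
choice) for laterals, optionally drifting with the birth day
(`setpoint_drift`). Headings relax toward the set-point with gain 0.2 per
0.05 cm step and are perturbed by `tortuosity_sd` (default 2°) of per-step
noise. Growth is clipped at the rhizotron walls, where a root stops. Each
deposited polyline point is stamped with its deposition day, so the system
at day *d* is exactly the prefix of the final system (monotone growth), and
all randomness derives from one integer seed.

The renderer draws the polylines as 5 px wide bands (about 0.5 mm at the
default 0.1 mm/px scale — the apparent width of a luminescent Arabidopsis
root trace) with intensity `peak_intensity * 2^(-age / age_decay_halflife)`.
The half-life default of 7 days is a free simulator knob: the decay of
signal in older tissue is a qualitative observation without a published
rate. Lines are drawn with *butt caps* (the stamped discs are clipped to the
step's axial extent): round caps would extend the mask half a line-width
past every tip and bias depth and width recovery. Soil occlusion erases
gaps whose positions are fixed per batch (soil particles do not move between
imaging days); speckle flips a fraction of pixels per frame; and a fixed
low-frequency background pattern — what the imager records with no
rhizotron present — is added identically to every frame of a batch.
`make_blank()` returns exactly that pattern.

What the simulator does **not** emulate: physiological responses (water,
nutrients, hormones), higher-order laterals, shoot signal, camera optics
beyond the fixed pattern, or non-translational frame motion. Passing tests
therefore demonstrate the correctness of the measurement chain on images
whose noise structure is idealized, not performance on any particular real
dataset.

## Preprocessing

`subtract_blank()` removes the fixed pattern by clamped subtraction.
`register_series()` aligns each frame to the first by the integer
translation maximizing normalized cross-correlation of a fixed template
region (translation only — the imaging rig moves rhizotrons, it does not
rotate them); frames whose correlation peak falls below `min_corr` are
flagged for screening rather than silently shifted.

`denoise_overlay()` turns each frame into a binary root mask and
accumulates masks over days. The intensity chain is applied in a fixed
order on a 0–255 working scale (16-bit input is rescaled first; the
constants are meaningless without a declared scale): subtract 1.5, clamp;
multiply by 3, clamp; subtract 8, clamp; 3×3 median; global threshold
(default 10 — a fixed threshold keeps the stage deterministic where an
adaptive method would not be); 3×3 median; one 3×3 binary erosion and one
dilation; removal of connected components below `min_particle_px` (default
20 px; 8-connected labeling). The day's mask is then OR-ed with the
previous day's output. This accumulation is load-bearing: tissue older
than ~4 half-lives falls below the threshold in later frames, and only the
running union keeps the full architecture visible. The chain is exactly
idempotent on simple shapes but not on branched masks — a 3×3 median fills
and shaves 1-px notches at junctions, touching a fraction of a percent of
boundary pixels — which is why the stability contract is stated as
"boundary-confined changes" rather than strict idempotence.

`tip_tracking()` isolates new growth between consecutive days as
`curr & !dilate(dilate(prev))`; the double dilation guarantees a 2 px
margin, so anything returned is genuinely new.

## Segment extraction

The measurement core decomposes a mask into *root segments*: locally
straight pieces described by the upper-left corner of their bounding box,
their skeleton arc length (1 per axial, √2 per diagonal step), and their
chord orientation in a 0–180° convention (0° down, 90° horizontal-right,
180° up; leftward chords are reflected and the left/right sense is kept as
a separate sign). The mask is thinned (Zhang–Suen), skeleton tips are
re-extended to the mask boundary (thinning retracts free line ends by
about half the line width, which would systematically shorten tips), the
skeleton is split at junctions, and arcs are cut greedily into runs of at
most `max_segment_len` (default 40 px). Junctions are detected by the
crossing number — at least three skeleton arms entering the 8-neighbourhood
— because raw neighbour counts misclassify the diagonal staircase pixels of
any thin skeleton as branch points and shatter the decomposition.
Components with fewer than 3 skeleton pixels are dropped as unmappable.

## Vectorization and cleaning

`format_segments()` folds the raw angle to the 0–90° gravity angle
(`theta` if ≤ 90, else `180 − theta`) and reconstructs directed endpoints
trigonometrically from the bounding-box anchor, chord length, raw angle,
and lateral sign. The bounding box alone cannot disambiguate left- from
right-pointing chords, so the extractor records the sign explicitly.

`clean_iterative()` removes non-root particles by day-wise iterative
clustering of segment start points. Day 1 is processed alone; each later
day is pooled with the retained set and the pass repeats: split the current
set in two by single-linkage clustering (`hclust`/`cutree`; for point sets
too large for a distance matrix, the equivalent minimum-spanning-tree
largest-edge cut in O(n) memory); if the between-group gap is at most
`proximity_max`, keep everything and stop. Otherwise the *anchor* group —
by default the one whose minimum |x − center_x| is smaller, i.e. nearer
the sowing position — is carried forward, and the other group is resolved
in a fixed order: fewer than `min_cluster_size` (default 4) points →
removed as `too_few`; gap above `hard_max_factor × proximity_max` (default
2×, "far too large") → `too_far`; scatter-matrix linearity
`λ1/(λ1+λ2)` below `linearity_threshold` (default 0.85) → `nonlinear`;
otherwise it is kept as a plausible distant root group. Every decision is
logged. Two points deserve emphasis:

* **Anchor direction.** The source procedure's text reads as if the group
  *farther* from center-x were kept, which contradicts the stated purpose
  (the seed is sown at top-center, so the true root is the near group).
  The default keeps the nearer group; `anchor = "farther"` reproduces the
  literal text.
* **Proximity default.** `proximity_max` must exceed twice
  `max_segment_len`: consecutive segment starts along one root sit about
  one segment length apart, and a single dropped run doubles that spacing.
  With the 40 px segment cap the default is 100 px (at 0.1 mm/px); a 50 px
  setting demonstrably fragments genuinely connected roots and then
  discards their deep, purely linear chains.

## Traits

Nine traits per plant per time point, in pixels (convertible via
`pixel_size`). Over all segment endpoints: width (max x − min x), depth
(max y − min y), convex hull area, and the depth-to-width ratio (reported
missing when width is 0). Center of mass is the length-weighted mean of
segment midpoints (a declared definition; the trait name alone does not fix
one). Total length is the sum of Euclidean vector lengths — deliberately
the chord, not the rasterized arc step count, which overestimates slanted
lines by 5–8%; total length is then an *underestimate* of true length, as
it must be: gaps between disconnected segments are never bridged, and where
two roots fuse in the image their overlap is counted once. At the default
branching density that fusion costs roughly 3–9% of true length depending
on developmental stage, which is why the trait should be read as visible
root length. Average angle is the length-weighted mean gravity angle, so
short segments contribute less. Per-day traits (count, length/day, average
angle of new growth) come from the tip-tracking masks, normalized by the
actual imaging interval; on the first imaging day every segment counts as
new.

As the root system fills the rhizotron, width saturates at 15 cm and depth
at 30 cm, so the depth-to-width ratio converges to the geometry's 2:1 —
a built-in check that the whole chain preserves extents (the package's
acceptance script measures exactly this on a 1500×3000 px simulation).

## Trait trajectories, heritability, clustering

Replicated time courses are summarized per genotype by the mixed model

y = β0 + (β1 + u_genot)·t + u_genoi + u_rep + e,

fitted by REML (`lme4`) with independent random intercepts per genotype,
random slopes per genotype, and random intercepts per replicate. REML was
chosen over the MCMC sampler used in the original analyses because it is
deterministic and the contract here is parameter recovery, not estimator
identity; an intercept-only null model provides the baseline AIC
diagnostic. Genotype fitted values are exactly linear:
`(β0 + u_genoi) + (β1 + u_genot)·t`, evaluated on the 0, 48, …, 336 h
grid to match the imaging frequency.

Broad-sense heritability uses a declared variance decomposition (no single
formula is canonical once a slope variance exists): the genotype-associated
variance on the observed grid is `var_geno_int + var_geno_slope · mean(t²)`,
and H² divides it by that quantity plus replicate and residual variances.
Simulation at the diversity-panel scale (93 genotypes × 6 replicates × 8
time points) recovers H² settings of 0.31 and 0.45 — the two printed
heritabilities for the angle traits, used here as simulation settings —
within a few points.

Trajectory clustering standardizes each day's column of the genotype × day
matrix of per-day average angles (z-scores; the scaling applied before
clustering is a declared choice), computes Euclidean distances, applies
between-group average linkage (UPGMA), and cuts the tree at 1.75. Labels
are ordered by decreasing cluster mean angle, so cluster 1 is the
consistently shallow group. Missing cells are imputed by the genotype's
row mean and recorded.

## Numerical and testing notes

* Problem sizes: the test suite exercises the full 1500×3000 px scale for
  the rhizotron-filling run (about a minute) and 200×400 px rhizotrons for
  fast unit coverage; trait-recovery checks use a mid-development system
  (12 days, imaging every 2 days), inside the usual 14–28 days-after-sowing
  imaging window but before heavy root crossing.
* Determinism: all simulator and model randomness flows from explicit
  integer seeds; RNG state is saved and restored around every seeded
  operation. Ties in the skeleton walk are broken axial-first in row-major
  order; ties in single-linkage merges follow `hclust`'s deterministic
  order.
* Known limitations: recovery of width is accurate to about ±2 px in the
  worst case because the printed median/opening chain shaves 1–2 px off
  diagonal tips; visible total length undercounts fused crossings (see
  above); the cleaner operates on segment start points only, and no
  parent–child topology is reconstructed — angles are relative to gravity,
  not to the parent root.
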