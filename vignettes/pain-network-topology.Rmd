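---
title: "Methods: resting-state network topology of pain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-state network topology of pain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painnet)
```

This vignette documents the models and procedures painnet implements, the
defaults it ships with and why, the numerical choices that matter, and
what the synthetic cohort generator does and does not emulate.

## From scan to network

A scan enters the pipeline as a frames × nodes ROI time-series matrix and
a paired frames × 6 motion trace (three translations in mm, three
rotations in radians). `build_adjacency()` applies, in order:

1. **Initial-volume discarding.** The first `drop_volumes` frames are
   removed from both objects (default 3 for raw scans, to discard scanner
   field-equilibration volumes; a 202-volume acquisition yields 199
   analysis frames).
2. **Framewise displacement.** For each frame-to-frame transition,
   FD = Σ|Δtranslation| + Σ r·|Δrotation| with r = `head_radius_mm`
   (default 50 mm). The rotational term converts angles to arc length on
   a sphere approximating the head; 50 mm is the convention commonly used
   with this atlas family. The radius is configurable because it is a
   modelling choice, not a measurement.
3. **Scrubbing.** Transitions with FD *strictly* greater than
   `fd_threshold_mm` (default 1.5 mm) flag a frame for exclusion. We drop
   the *latter* frame of a flagged transition — the minimal reading of
   "excluding high-motion time points" — and expose `drop_preceding` for
   the stricter variant that also drops the frame before. A displacement
   of exactly 1.5 mm is retained.
4. **Correlation and Fisher transform.** Pearson correlations over the
   retained frames (at least 3 required) are mapped through
   z = arctanh(r); the diagonal is set to 0. Off-diagonal |r| = 1 is an
   error (it would map to ±∞), as is a zero-variance node: silently
   propagating degenerate values into graph metrics would be worse than
   failing with the node named.

The motion covariate `mean_motion()` is the mean absolute frame-to-frame
change over the whole scan, averaged across the six parameters with
rotations converted to mm by the same radius, so the six degrees of
freedom are commensurable before averaging.

## Graph metrics

Weights are converted to lengths by L = 1/w. Weights that are zero or
negative (after the negative-weight policy) are treated as absent edges.
Two policies are available for negative Fisher-z weights:

- `"zero"` (default): negative weights are dropped. This matches the
  assumption of the standard weighted-efficiency and weighted-betweenness
  routines used in this literature, which expect non-negative weights.
- `"abs"`: magnitudes are used, for sensitivity analyses.

This is the single most result-relevant choice the underlying analysis
leaves unstated, which is why it is exposed in the configuration and
recorded in every run manifest rather than hard-wired.

**Global efficiency** is the mean over ordered node pairs of the inverse
weighted shortest-path distance, with 1/∞ = 0 for disconnected pairs.
**Betweenness centrality** uses Brandes' dependency accumulation over
Dijkstra shortest-path trees, reported on the unordered-pair scale, so a
star's centre scores (n−1)(n−2)/2. Shortest-path length ties are judged
at a relative tolerance of 1e-10: with continuous weights exact ties are
a measure-zero event, but accumulated floating-point error can make
genuinely tied two-hop paths differ in the last bits, and the tolerance
keeps path counts stable. Both metrics are validated in the test suite
against independent oracles (Floyd–Warshall pair averages, exhaustive
simple-path enumeration, and igraph) to 1e-9 on hundreds of random
graphs.

**Per-network summaries** (`summarize_topology()`): whole-brain GE; per
subnetwork, GE of the *induced subgraph* (paths confined to the
subnetwork; the alternative `"restricted"` mode averages whole-brain
inverse distances over subnetwork pairs) and the mean z-scored BC. BC is
computed once on the whole-brain graph and z-scored per participant
across all nodes *before* subnetwork averaging. This order is forced by
the arithmetic: z-scoring within a subnetwork would make every
subnetwork mean identically zero, which would contradict the nonzero
group means such analyses report. For the same reason the whole-brain
mean z-BC is 0 by construction and is not reported. The z-score uses the
population (n-denominator) standard deviation by default; the sample-sd
variant is a configuration switch, since either convention is defensible
and the choice is not recoverable from the literature this design
follows.

## Node sets

Three named sets ship with the package: `whole_brain` (264 atlas nodes),
`dmn` (58 nodes) and `pain` (16 nodes, the positive-weight regions of the
neural pain signature, with their region names). The *cardinalities and
names* are fixed; the concrete index assignment of the pain and DMN sets
into the 264-node ordering is a synthetic placeholder, because the
published atlas tables are not redistributed with this package. All
computation is index-set-generic: users with real data supply a JSON
definition file (0-based indices; converted to R's 1-based indexing on
load) and nothing else changes. Sphere-ROI extraction from 4D NIfTI
volumes (`extract_roi_timeseries()`, voxel-centre-in-sphere membership in
world coordinates, default radius 5 mm) is an optional convenience for
ingesting preprocessed volumes; radius and aggregation were not
specified upstream, so it makes no claim of matching any particular
extraction.

## Statistics

- `mann_whitney()` reports U for the *first* sample (the convention
  matters when comparing against published U values) with an exact
  enumeration p when n₁·n₂ ≤ 400 and the data are tie-free, else a
  tie-corrected normal approximation.
- `chi2_2x2()` is the uncorrected Pearson statistic; no Yates correction,
  which is required to reproduce the printed worked example
  (χ²(1) = 6.080 for 18/24 patients vs 11/27 controls with chronic pain).
- `ancova_group()` fits `dv ~ covariate + group` per dependent variable
  and tests the group term; with two groups and no interaction the
  sequential, type-II and type-III tests coincide, so the implementation
  uses the explicit nested-model F. Wilks' lambda across the DV set comes
  from the corresponding multivariate fit. With 27 + 24 observations and
  one covariate the group term has df (1, 48). A zero-variance covariate
  degrades gracefully to one-way ANOVA. Patient ON and OFF sessions are
  compared against controls in separate two-group models, mirroring the
  df structure of the design this follows; treating a patient's two
  sessions as independent observations is a known statistical caveat of
  that design, inherited deliberately rather than resolved.
- `forward_stepwise()` implements hierarchical forward selection with a
  forced covariate block: step 1 is the covariate-only model; at each
  later step the candidate with the smallest entry p enters if
  p ≤ `p_enter` (default 0.05, two-sided, no removal). A removal
  threshold (`p_remove`, e.g. 0.10) is available for the common
  statistical-package default, but pure forward is the default because
  that is what "forward stepwise" specifies. Standardized coefficients
  are B·sd(x)/sd(y). No multiple-testing correction is applied anywhere
  (α = 0.05 per test, matching the analysis design); the run manifest
  records the number of tests so users can judge for themselves.

## The synthetic cohort generator

`cohort_design()` describes the cohort the pipeline is tested on:
24 patients scanned twice (ON and OFF) and 27 controls scanned once — 75
subject-sessions. Each scan's latent signal is multivariate normal with
unit variances, correlation `baseline_r` (default 0.1) between all node
pairs and `pain_r` (defaults: patients 0.4, controls 0.3) within the
designated pain block, plus independent observation noise of SD
`noise_sd` (default 0.3). The implied covariance is checked for positive
semi-definiteness up front and invalid parameter combinations are
rejected with the offending values named.

Motion is AR(1) drift per parameter (coefficient 0.95, innovation SD
0.02 mm for translations and 0.02° — stored in radians — for rotations)
with transient spikes of `motion_spike_mm` (default 2 mm, above the
scrub threshold) added to a random translation axis with per-frame
probability `motion_spike_prob` (default 0.02). These values are chosen
so that realistic scans exercise both scrubbing branches: typical FD sits
well below 1.5 mm and spikes exceed it.

Pain scores: the two CAS scores are drawn from group-specific normal
distributions clipped to the instrument range [0, 100], with group means
and SDs matching the magnitudes reported for this kind of cohort;
chronic-pain status is a per-subject Bernoulli draw (0.75 patients,
0.407 controls). The NWC score is

nwc = round(max(0, beta_pain · GE_true + ε)),  ε ~ N(0, pain_noise_sd²)

where **GE_true is the pain-network GE of the scan's noise-free latent
series**. This definition matters: the population correlation block is
constant within a group, so defining GE_true from it would plant *no*
recoverable within-group association. Using the realized latent series
gives GE_true finite-sample variation across subjects that the estimated
GE tracks closely (r ≈ 0.96 at the scaled design below), which is exactly
the property a recovery experiment needs. The default generator does not
attempt to match published per-subject pain-score distributions beyond
these group-level magnitudes — those distributions are not available.

What the generator does **not** emulate: haemodynamics, physiological
noise, scanner artefacts, spatial autocorrelation, atlas geometry, or any
nonstationarity. Passing tests therefore demonstrate that the pipeline's
computations and inferences are correct for data with the assumed
block-covariance structure — not that the scientific conclusions of any
particular real-data analysis are correct.

## Problem sizes and the recovery experiment

The test suite and the acceptance script run the Monte-Carlo experiments
on a scaled cohort — 30 nodes with an 8-node pain block, 199 frames,
full-size groups (24 + 27) — which preserves the statistical structure
(df, group layout, planted association) while keeping a 200-cohort
experiment inside a few minutes on one CPU. At this design the
within-group SD of GE_true is ≈ 0.036, so the planted arm uses
`beta_pain = 60` against `pain_noise_sd = 1`, a signal-to-noise of ≈ 2.2
on the latent scale; the null arm sets `beta_pain = 0` with
`pain_noise_sd = 6` so NWC has realistic spread. With two null candidates
and entry at p ≤ 0.05, the expected no-selection rate is near
(1 − α)² ≈ 0.90, and the GE-specific false-selection rate stays below
10%.

## Degenerate inputs and edge cases

- Fewer than 3 retained frames, a zero-variance node, |r| ≥ 1
  off-diagonal, non-finite motion: errors naming the offending object.
- Graphs: GE needs ≥ 2 nodes, BC ≥ 3; an edgeless graph has GE 0 and the
  all-zero BC vector z-scores to all zeros (zero-spread rule).
- A scrub threshold of 0 removes every frame after the first on any
  realistic trace and the run fails loudly at the correlation
  precondition — by design, no silent fallback.
- All randomness flows through explicit integer seeds; identical design
  and seed reproduce cohorts bit for bit.

## Known limitations

- The shipped pain/DMN index assignments are placeholders (see above);
  real-data use requires the true atlas indices.
- Nuisance regression, bandpass filtering, global-signal regression and
  partial correlations are out of scope: the connectivity step is
  deliberately the plain scrub → correlate → Fisher chain.
- The ON/OFF non-independence caveat in the group comparisons, inherited
  from the mirrored design.
- Weighted shortest paths in pure R are O(n³) per scan; fine up to a few
  hundred nodes (a 264-node scan takes on the order of a second), but
  this package is not tuned for voxel-level graphs.
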