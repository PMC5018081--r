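---
title: "Methods: cap mesenchyme track analysis and the tip-distance model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cap mesenchyme track analysis and the tip-distance model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capmotion)
```

# The problem

Nephron progenitor (cap mesenchyme, CM) cells swarm around the tips of the
branching ureteric epithelium in the developing kidney. Live imaging of
cultured embryonic kidneys yields manually tracked 3D positions of CM cells
at 15- or 20-minute intervals, together with a point-cloud rendering of each
ureteric tip volume and a manually tracked "tip end" per tip. Three
complications stand between those raw tracks and any statement about cell
motility:

1. **Mitosis.** Tracking software follows a dividing cell into both
   daughters under one track id without marking the branch point.
2. **Drift.** The tissue moves and the tips grow, so a cell's displacement
   mixes intrinsic motility with transport by its local niche.
3. **Geometry.** "Toward the tip" is only meaningful relative to the
   nearest point of a complex, moving surface.

`capmotion` implements the full post-processing chain — branch resolution,
tip-relative geometry, spatially heterogeneous drift correction, motility
statistics, and a steady-state convection-diffusion model of the cell-to-tip
distance distribution — plus a synthetic track generator with known ground
truth so every stage is testable without the original imaging data.

# Branch resolution

Within one track, positions at consecutive time steps are associated under
the tracking degree constraints: at most one parent per position, at most
two children per parent. Among feasible matchings we take the lexicographic
optimum: first minimize the number of unmatched endpoints (track starts at
t+1 plus terminations at t), then the total Euclidean distance over matched
pairs. Given a maximal matching this also minimizes bifurcations, so
spurious divisions are never introduced when a one-to-one association
exists. The optimum is found exactly by a min-cost assignment in which each
parent is duplicated (capacity two) and dummy rows/columns absorb unmatched
endpoints at a penalty exceeding any achievable distance sum; a dense
Jonker-Volgenant solver computes the assignment, and the tests check it
against exhaustive enumeration on hundreds of random instances.

Two genuinely open choices were resolved as follows:

* **Per-frame-pair optimization.** The matching objective is stated over
  the whole track but is solved here independently per consecutive frame
  pair. A global multi-frame formulation would be an integer program with
  no clear gain on real division geometries (daughters start close to the
  parent); the per-pair optimum is exact for each interval and
  deterministic.
* **No gap closing.** A cell absent from an intermediate frame splits the
  track (with a warning) rather than being bridged. Only consecutive-frame
  association is defended by the data model.

Exact distance ties (e.g. coincident daughters) are broken by parent then
child index after putting each frame's spots in canonical coordinate order,
so resolution is invariant to input row order.

# Tip-relative geometry

For every spot, the nearest point of the tip spot cloud at the same time
step defines the tip vector, tip distance, and the horizontal/vertical
classification (a spot is *horizontal* when the vertical angle of its tip
vector is strictly less than 45°, i.e. |dz| < sqrt(dx² + dy²); the boundary
case is vertical). All tip-context fields are computed on **raw** positions:
the tip cloud is itself uncorrected, so mixing corrected cell positions with
uncorrected tip geometry would be inconsistent. Nearest-neighbour queries
are exact (vectorized linear scan; clouds hold tens to hundreds of points).

Attachment annotation (periods in which a cell extends a process onto the
epithelium) is keyed by unbranched segment id with first/last time steps;
spots on annotated segments are `attached` inside any interval, `free`
outside, and `unannotated` elsewhere.

# Drift correction

For each interval between consecutive steps, each cell's movement is
corrected by subtracting a weighted average of the tip-end-track movements,
with weights proportional to the inverse square distance from the cell to
each tip **at the interval's start step** (the start is used for causality
and determinism). The correction applies to the horizontal components only;
z is passed through unchanged. Corrected positions are rebuilt by anchoring
each segment at its first raw position and accumulating corrected
movements.

Properties guaranteed by construction and enforced by tests:

* a uniform translation of cells and tips (bulk drift) changes nothing;
* a cell that rides a single tip exactly has zero corrected movement;
* the corrected z series equals the raw z series;
* as a cell approaches one tip its weight on that tip tends to one.

Tips missing at either end of an interval are excluded and the remaining
weights renormalized; a coincidence guard (ε = 1e-9 µm) gives a touching
tip full weight. Crops are analysed independently — cells never weight tips
from another crop.

# Motility statistics

* **MSD** is computed per track in 3D, `mean |p(t+τ) − p(t)|²` over all
  valid t, then averaged unweighted across tracks, separately for 15- and
  20-minute data (a lag in steps is a different physical time in each
  group). Tracks shorter than a lag are excluded at that lag, never counted
  as zero.
* **Velocity autocorrelation** uses horizontal step vectors only, per-track
  normalized by the mean squared single-step horizontal displacement.
  Axial resolution is markedly poorer than lateral and produces "jitter":
  a spurious negative single-step autocorrelation in z. The generator
  reproduces this (independent per-frame z measurement noise) and the
  tests confirm horizontal statistics are unchanged by any z perturbation.
* **Instantaneous speed** is the horizontal step length in µm per time
  step. Speed heterogeneity between tracks is assessed by comparing nested
  linear models, speed ~ sample versus speed ~ sample + track, with an
  ANOVA F-test; the percentage reduction in residual sum of squares is the
  share of speed variability attributable to track identity.
* **Tip-directed movement** projects the drift-corrected movement over the
  subsequent step onto the unit vector toward the nearest tip point
  (positive = toward the tip). The projection is used instead of the change
  in distance because near a complex surface random motion does not change
  the distance symmetrically. Both vectors are taken in 3D, which keeps the
  invariant |m| ≤ |movement|; a `horizontal = TRUE` flag provides the
  xy-only variant for sensitivity analysis. Spots within 1 µm of a lateral
  crop edge are excluded (strictly less than 1 µm; the margin itself is
  kept) because their outward moves can leave the imaged volume. Moves are
  grouped at 10 µm initial tip distance and each group's mean is tested
  against zero with a classic one-sample two-sided t-test; a far-field
  linear regression of the projection on initial distance (beyond 15 µm)
  tests whether attraction varies with distance.

All of these constants — 1 µm margin, 10 µm split, 15 µm threshold, 45°
angle — are configuration defaults ([pipelineConfig()]), not hard-coded.

# The tip-distance model

Radial motion relative to the tip surface is modelled as diffusion D
(independent of distance) plus a directed radial velocity v(d), with
k(d) = v(d)/D; positive k is repulsion from the tip, negative attraction.
Treating the observed distance distribution as stationary, the zero-flux
steady state of the conservation equation
∂y/∂t = ∂/∂d (D ∂y/∂d − v y) is

y(d) ∝ exp(∫₀^d k(u) du).

Only the ratio k = v/D enters this density, so v and D are never estimated
separately — no function in the package pretends otherwise. k(d) is the
four-parameter piecewise-linear profile: constant k1 below d1, constant k2
above d2, linear between. Its integral is available in closed form
(piecewise quadratic), and the likelihood of n observed distances is
Σ cumulativeK(dᵢ) − n log Z with Z obtained by adaptive quadrature,
stabilized by subtracting the exponent's maximum (which lies at an
endpoint, a breakpoint, or the interior zero crossing of k).

**Fitting.** The likelihood is maximized over transformed parameters
(log d1, log of the d1→d2 gap, k1, k2), each start running Nelder-Mead
followed by a BFGS polish; multiple data-driven starts (density peak for
d2, histogram log-slopes for k1 and k2) guard against local optima.
Standard errors come from the inverse observed information. The Hessian is
computed by central differences on the original parameter scale with
parameter-scaled steps (5e-3 relative): the objective is evaluated through
adaptive quadrature, so steps must be large enough that quadrature noise
does not dominate the second difference. When the fitted d1 sits at the
zero boundary, the information matrix is genuinely near-singular in the
(d1, k1) directions — the near-field segment covers almost no data — and
the corresponding standard errors are reported as `NA` or very large
rather than disguised. `simplifyProfile()` collapses d1 to 0 when
|d1| < 1.96·SE(d1) (reported ± values are treated as standard errors),
giving the two-piece linear profile; it is idempotent and keeps a
significant d1 unchanged.

`d_max`, the domain bound of the density, defaults to the maximum observed
distance and is configurable because Z depends on it. The distances fitted
by the pipeline are all spots' nearest-tip distances (raw positions); edge
exclusion can be applied via a flag but is not the default.

# The synthetic generator

`syntheticScenario()` defaults define the simulated study conditions: a
160 × 160 × 60 µm crop, 3 tips of radius 5 µm drifting at 0.3 µm/step with
constant random horizontal headings, 200 founder cells followed for 70
steps of 20 minutes, division probability 0.005 per cell-step, and z jitter
of 1.5 µm. Per step, a cell moves by (i) the inverse-square-weighted drift
of the tips, (ii) radial convection D·k(d) along the line to the nearest
tip centre, with k evaluated at the distance to the tip *surface* (centre
distance minus tip radius) so the generator's steady state lives on the
same distance scale the analysis measures, and (iii) isotropic Gaussian
noise with per-axis σ = sqrt(2D). That coupling makes the radial diffusion
consistent with the 1D steady-state model (per-step radial variance 2D).
The default truth profile is the simplified fitted profile
(k1 = 0.293/µm, k2 = −0.098/µm, d2 = 14.95 µm, d1 = 0) and D = 1.5
µm²/step, which yields near-surface repulsion and far-field attraction of
a few tenths of a µm per step — the magnitudes seen in real CM tracks.
Founders are seeded at steady-state distances; cells reflect at the crop
bounds (reflections are counted in the ground-truth ledger). Divisions
duplicate a cell with a ~1 µm offset. Tracks without divisions are
annotated for attachment wherever their observed tip-surface distance
stays below 3 µm for at least two consecutive steps, so the annotation's
track id names an unambiguous unbranched segment.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: the tip is a smooth drifting sphere, not a
growing branching surface; convection is purely radial from tip centres
while the analysis measures distances to cloud points (a deliberate mild
mismatch that exercises robustness); cell-cell interactions, confinement by
neighbouring tissue, and heterogeneous per-cell speeds are absent (so the
speed-heterogeneity statistic is near zero on simulated data and its
recovery is tested on directly constructed speed tables instead); and the
real z-resolution artefact is only approximated by Gaussian measurement
noise.

# Problem sizes and numerical choices

The test suite and examples use scenario sizes chosen so the full pipeline
runs in seconds (40-200 cells, 12-70 steps) while keeping every statistical
check at conventional power: 500-track ensembles for the Brownian MSD
closed form, 1000 null replicates for the t-test calibration, 20 scenario
replicates for the near/far sign-pattern power check, and 20,000 sampled
distances for maximum-likelihood parameter recovery. Steady-state sampling
inverts the CDF on a 16,384-point grid. All stochastic code takes an
explicit seed; identical scenario and seed reproduce byte-identical CSV
output.

# Known limitations

* The per-frame-pair matching is optimal per interval, not over the whole
  track; pathological geometries could differ from a global optimum.
* The 1D steady-state model ignores the curvature of the tip surface and
  boundary effects, so profiles fitted to fully simulated (3D, reflecting)
  datasets are biased relative to the generator's truth profile; exact
  recovery is only expected — and tested — on distances drawn from the 1D
  density itself.
* d1 is weakly identified whenever the true profile has d1 ≈ 0; its
  standard error is then unstable by nature.
* Attachment annotation in the generator is restricted to undivided
  tracks.
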