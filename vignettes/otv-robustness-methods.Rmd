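---
title: "Margin-based and robust target volumes for proton PBS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Margin-based and robust target volumes for proton PBS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The planning problem

Stereotactic proton pencil-beam-scanning (PBS) therapy of pancreatic tumors
delivers an ablative prescription (here 33 Gy(RBE) in 5 fractions) with the
duodenum — a serial organ at risk — abutting the target. Proton dose
distributions are exquisitely sensitive to two error sources: rigid setup
errors (millimeters) and range errors from the CT-to-stopping-power
conversion (conventionally ±3.5%). Margin design must absorb both without
flooding the duodenum.

`pbsplan` implements, on fully synthetic phantoms, three competing
spot-weight optimization schemes and the machinery to compare their
robustness:

* **OTV_2mm / OTV_5mm** — uniform geometric expansion of the GTV used only
  during optimization;
* **OTV_WET** — a beam-specific expansion: along each field's rays the GTV
  interval is extended distally and proximally by 3.5% of the local
  water-equivalent thickness (WET), converted back to geometric millimeters
  through the local stopping power, plus a 2 mm lateral (beam's-eye-view)
  setup margin;
* **RO** — robust minimax optimization of the raw GTV over an explicit
  scenario set (setup shifts of 2 mm and range scalings of ±3.5%),
  minimizing the worst-case objective.

Evaluation follows the protocol's three instruments: the 42-scenario passing
rate (a scenario passes when at least 95% of the GTV receives the full
prescription), the 8-scenario DVH bandwidth

$$ W_d \;=\; \frac{2\sqrt{\sum_{i=1}^{N} (D_i - D_\mathrm{nominal})^2 / (N-1)}}{D_\mathrm{nominal}} \times 100\%, $$

and the dose spread function (DSF) — the analytic derivative of a smooth fit
to a line dose sampled across the 100%-isodose/duodenum abutment, summarized
by the full widths of its peak at 50% (FWHM) and 20% (FW20M) of maximum.

## The synthetic phantom

The generator (`make_phantom()`) emulates the study geometry rather than any
patient: a water elliptic-cylinder body (semi-axes 140 × 110 mm) on air, an
ellipsoidal GTV (default 16 mm radius, 17.2 mL — inside the study's
7.6–82.2 mL range) whose center sits 155 mm from the posterior surface so
that the distal GTV surface lies 169–178 mm of water-equivalent depth from
the entrance of each posterior-oblique field (gantry 210° and 150°), a
curved duodenum-surrogate tube (9 mm radius) abutting the GTV anteriorly
(gap 0 mm, because the DSF analysis targets exactly that abutment), and
optional stomach/kidney/cord blobs whose placement jitter is the only
randomness (one seed). Tissue HU values are soft-tissue-like (0–40 HU); the
default four-node calibration curve (air, lung-like, water, bone-like) maps
0 HU to RSP 1 exactly, so water-equivalent and geometric depths coincide in
the body to within ~2%.

The default grid is 2 mm isotropic, 160 × 128 × 64 voxels (320 × 256 ×
128 mm): large enough to contain the body ellipse and the full beam paths,
small enough that the complete three-scheme study runs on a desk machine in
minutes. Patient axes are fixed once: x = patient-left, y =
patient-posterior, z = superior; gantry 180° is the posterior field
travelling along −y.

What the phantom does **not** emulate: heterogeneous anatomy along the beam
path (bone, gas), breathing motion, and patient-to-patient anatomical
variation. Passing tests on this phantom therefore demonstrate the internal
consistency of the margin/optimization/evaluation machinery under the stated
uncertainty model — not clinical performance on real CTs.

## Water-equivalent thickness

`trace_wet()` integrates RSP along the beam direction with fixed-step
midpoint sampling (step 0.5 mm ≤ half the voxel spacing), treating RSP as
piecewise-constant per voxel — the standard treatment of CT-derived stopping
power. This makes the fast tracer converge to the exact voxel-intersection
(Siddon) line integral within one step times the maximum RSP, which the test
suite verifies against an independent Siddon implementation on random grids.
Air upstream of the body is integrated as-is (RSP 0.001), not zeroed.

## Target volumes

`expand_uniform()` applies the center-sampling convention: a voxel joins the
expansion when its center lies within the margin of the voxelized target
*solid*. The solid is represented by half-voxel supersampling of the mask;
a plain center-to-center distance transform systematically under-covers
(the true surface lies up to half a voxel beyond the outermost centers),
which at 1 mm spacing already distorts a 2 mm concentric-sphere expansion by
~7% in volume. With supersampling the expanded volume tracks the analytic
concentric-sphere value to a few percent.

`expand_beam_specific()` works on a beam-aligned lattice at half-voxel
resolution: per lateral ray it finds the proximal/distal WET of the target,
marches the 3.5%-of-WET water-equivalent margins through the local RSP to
geometric lengths, then dilates laterally with a 2 mm disk per depth slab
(beam's-eye-view directions only). Margins are per-ray by default — the
beam-specific construction is intrinsically ray-wise — with a worst-case
(uniform per beam) mode behind `per_ray = FALSE`. The proximal margin uses
the proximal WET (and the distal margin the distal WET); in uniform water
the distal extension equals fraction × distal depth exactly, which the tests
assert against the closed form.

Overlap exclusion (`exclude_overlap()`) removes named OARs from an OTV with
GTV precedence. The *default study configuration does not exclude* the
duodenum overlap from the optimization targets. This was a deliberate
deviation decided after measuring its mechanism in this engine: the analytic
kernel's distal falloff (80%–20% in ~2.8 mm, no nuclear halo) is sharper
than a commercial Monte Carlo SOBP edge, so carving the abutting duodenum
out of the OTV leaves the distal-margin region behind the abutment with no
coverage objective and no energy layers at all — range-scaled scenarios then
strip several percent of GTV coverage there, which a broader physical
falloff would partially refill. Keeping the overlap inside the target while
penalizing the duodenum at the prescription level (the direct translation of
its V(33 Gy(RBE)) < 1 cm³ constraint) reproduces the protocol's categorical
behavior; exclusion remains available via `study_config(exclude_oars=)`.

## Dose engine

The per-spot kernel factorizes into a depth factor and a lateral factor.
The depth factor `bragg_depth_dose(R, z)` is an analytic single-peak curve:
entrance plateau at 30% of peak, proximal Gaussian build-up (σ = 0.07 R),
maximum exactly at the water-equivalent range R, and a distal Gaussian
falloff with 80%–20% width 2.8 mm at R = 160 mm, scaling linearly with R —
under 5% of range beyond the peak the dose is below 1% of it. Only the
qualitative Bragg behavior plus exact linearity and range-scaling contracts
matter for the study logic; no nuclear buildup, halo or heterogeneity
scattering is modeled. The lateral factor is a 2-D Gaussian of fixed σ =
5 mm in the beam's-eye plane (spot-size optimization is out of scope).

Spots sit on a hexagonal lateral lattice (5 mm constant) covering the
target's beam's-eye-view projection plus one spacing, with energy layers
every 5 mm of WET spanning the target's proximal-to-distal interval.
Scenario perturbations enter the influence computation as a rigid shift of
the sampled voxel positions plus a multiplicative scaling of the per-voxel
WET (equivalent to global RSP scaling) — identically during optimization and
evaluation. Influence entries below 10⁻⁴ of their spot's maximum are
dropped and matrices are stored sparse.

## Optimization

The objective is a voxel-count-normalized sum of one-sided quadratic
penalties (minimum / maximum) and a quadratic uniform-dose term. Defaults
follow what a planner does to meet protocol goals: minimum-dose at 101.5% of
prescription with dominant weight (so the optimization volume's *edge*, not
the distal falloff, carries the prescription — with margins sized exactly to
the range scaling, edge coverage is what survives the worst scenarios), a
uniform term at prescription, a 108% target cap, and the duodenum max-dose
penalty at prescription. Weights are exposed in `study_config()`.

Single-field optimization solves each field independently for its equal
share of the prescription (projected-gradient descent with backtracking;
nonnegative weights after every iteration; cap 500 iterations, relative
tolerance 1e-5 — the solver is deterministic, so no seed is involved).
Robust optimization minimizes, per field, the maximum objective over the
scenario set by iterative worst-case selection: solve against the active
scenario set, re-evaluate all scenarios, add the new worst one, repeat while
the worst case improves. The optimization set defaults to 21 scenarios
(nominal + 6 cardinal shifts, × 3 range scalings); the protocol text also
mentions a 42-scenario composition, selectable via
`study_config(ro_scenarios = 42)`.

Finished plans are renormalized by a single factor so that nominal GTV D98
equals the prescription — the protocol's nominal coverage goal — before any
evaluation.

## Scenario sets and evaluation

`make_scenarios()` builds three documented compositions, all shifts with
Euclidean norm exactly equal to the setup magnitude (2 mm is read as a total
displacement tolerance, so diagonal shifts are normalized, not per-axis):

* `eval42`: 14 shifts (nominal; anterior, posterior, right, left, inferior;
  8 diagonals) × range scalings {0.965, 1, 1.035} — 42 scenarios. The
  protocol's literal cardinal list omits "superior"; a 15-shift variant is
  available via `include_superior = TRUE`.
* `ro21`: nominal + 6 cardinal shifts, × 3 scalings — 21 scenarios. Note
  this set is *not* a subset of the default `eval42` (it contains the
  superior shift); it is contained in the 15-shift evaluation variant.
* `bandwidth8`: 6 cardinal shifts at nominal range, plus under- and
  over-range at zero shift — 8 scenarios.

`evaluate_passing()` recomputes the GTV dose under every scenario and
reports the percentage of scenarios with GTV V(prescription) ≥ 95%.
`perturbed_dvh_family()` yields one DVH per scenario (nominal first);
`bandwidth()` evaluates the W_d statistic with N counting the perturbation
scenarios only — the nominal value is the reference, not a sample, which is
how "standard deviation from nominal" reads.

## DVH and DSF numerics

DVHs are counting histograms (bin width 0.05 Gy(RBE)); D_q interpolates
linearly between bin edges, and V_d is returned both relative and absolute.
Bandwidths are evaluated at D98 and D50 for the target and V20 for the
duodenum.

For the DSF, the line dose is sampled by trilinear interpolation along a
segment across the target-duodenum abutment. Two locators exist:
`locate_abutment_line()` follows the closest approach between the 100%
isodose surface and the OAR (through the overlap centroid when they
intersect) and serves single-plan inspection; for comparisons *between*
plans, `abutment_axis()` provides one anatomy-anchored line (through the
GTV-duodenum contact along the centroid axis) used for every scheme — on
discrete surfaces the per-plan closest-approach point moves with the plan,
which would confound falloff steepness with sampling location. The study
runner uses the anatomical axis. The profile is fitted with a
Gaussian-CDF (erf) falloff family, chosen over a generalized logistic
because the DSF of an erf profile is an exact Gaussian with closed-form
widths — a logistic fitted to a Gaussian-blurred edge misestimates the
derivative's FWHM by roughly 12%, while the erf family recovers the
generating σ to well within the 5% the test suite demands. Logistic and
smoothing-spline families remain selectable. Fits are initialized by a
deterministic grid search over (center, width) with linear least squares for
the amplitude, then polished with Levenberg–Marquardt; a fit whose RMS
residual exceeds 5% of the falloff amplitude is flagged and only the raw
numeric derivative is reported. Two width conventions appear in the field —
widths of the DSF peak at 50%/20% of its maximum, and the distance for the
fitted profile itself to drop from the plateau (crossing taken at 98% of the
plateau level) to 50%/20%; both are computed and reported distinctly
(`fwhm`/`fw20m` vs `w100_50`/`w100_20`), never conflated.

## Problem sizes and determinism

The shipped defaults run the full three-scheme study — phantom, WET maps,
OTVs, three optimized plans, 42-scenario evaluations, bandwidths and DSF —
in roughly five minutes on one core; the test suite re-derives its expected
values from closed forms, brute-force oracles (Siddon ray walk, counting
DVH, transcription of the bandwidth formula) and small analytic fixtures.
Everything downstream of the phantom seed is deterministic: the solver has
no random component and scenario sets are fixed lists, so re-running a study
with the same configuration reproduces its CSV outputs byte for byte.

## Known limitations

* The dose kernel is a caricature of a measured Bragg curve: no nuclear
  halo, no heterogeneity-driven lateral disequilibrium, constant lateral σ.
  Absolute OAR metrics (e.g. duodenum V20 in cm³) are engine-specific;
  orderings between schemes are the meaningful output.
* The phantom is near-homogeneous water; scenario shifts therefore act as
  clean WET translations. Real heterogeneity would couple setup and range
  errors nonlinearly.
* RBE is a constant folded into Gy(RBE); no LET or variable-RBE modeling.
* Beam angles are fixed (210°/150°); beam-angle optimization is out of
  scope.
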