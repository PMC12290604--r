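---
title: "Methods: laminar VASO/BOLD analysis and the layered-cortex simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laminar VASO/BOLD analysis and the layered-cortex simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasodyn)
```

`vasodyn` analyses cerebral-blood-volume (VASO) and BOLD responses across
cortical depth for a symmetric slice-selective slab-inversion acquisition,
and ships a generative simulator so that every analysis stage can be
validated against known ground truth. This vignette is the package's account
of the underlying models, the parameters that matter, the numerical choices,
and what the passing tests do and do not establish.

## The acquisition and sampling model

One acquisition cycle consists of four equally long blocks of 0.785 s:
inversion delay, blood-nulled EPI readout, an additional delay, and the BOLD
EPI readout. Each cycle therefore delivers one nulled and one BOLD volume at
a volume-pair TR of 3.14 s. Stimulus onsets are systematically jittered over
the four block phases of the cycle; assuming response stationarity, trials
pooled across jitters sample the response every `3.14 / 4 = 0.785` s. The
`acq_scheme()` object records this arithmetic (`cycle_s()`, `eff_dt()`), the
readout block of each contrast (nulled at block 2, BOLD at block 4), and the
inversion-timing metadata that the sampling model itself does not use.

Stimulus designs (`make_design()`) present each of the five durations
{1, 2, 4, 12, 24} s exactly once per jitter and run. Rest periods are
duration-matched: short inter-trial intervals {10, 12, 14, 20, 24} s or long
ones {20, 22, 24, 30, 40} s. Long-ITI designs reuse one trial pattern for
all runs of a participant, which permits run averaging before
BOLD-correction; short-ITI patterns are shuffled per run. Runs are padded
with 30 s of rest at both ends so the baseline window is always available.
Onsets are placed on the jitter grid by construction, so trial windows
(stimulus plus its rest) never overlap.

## The generative signal model

The simulator assigns each voxel of a synthetic cortical ribbon to one of
four hemodynamic compartments: three equivolume gray-matter depth thirds
(deep, middle, superficial) and vessel-dominated voxels placed as tubes in
the CSF just outside the GM/CSF boundary. Per compartment `c` and contrast,
the response to a stimulus of duration `d` is a saturating convolution

    r(t) = a_c * min( [boxcar(d) * gamma_variate](t), cap_c )

with a gamma-variate kernel parameterized by onset delay, mean and sd
(`shape = (mean/sd)^2`, `scale = sd^2/mean`) — the same family as the GLM's
HRF, so the convolution has the closed form of a difference of gamma CDFs
and analytic peak times and amplitudes can be recorded as ground truth. The
hard ceiling `cap` is the simplest mechanism that produces a saturating
vessel response; with `cap = Inf` the response is exactly linear in
amplitude and nondecreasing in duration, which the property tests exploit.

Cycle `i` of a run yields, per voxel,

    S_bold[i]   = S0_b * (1 + delta(t_b[i]))
    S_nulled[i] = S0_n * (1 - v(t_n[i])) * (1 + g * delta(t_b[i]))

where `v` is the compartment's CBV response sampled at the nulled readout,
`delta` its BOLD response, and `g` the contamination gain (default 1).
The T2* contamination is treated as *quasi-static within a cycle*: a single
BOLD state, evaluated at that cycle's BOLD readout, multiplies both volumes.
This is a modelling choice: the two readouts are only 1.57 s apart and the
BOLD response varies smoothly on that scale, and the choice makes the
dynamic-division correction an exact inverse of the generative model —
which is what turns the whole pipeline into a testable recovery problem. A
contamination evaluated separately at the nulled readout would differ by a
term of order `g * delta'(t) * 1.57 s` that no division-based correction
could remove, leaving the "exact" behaviour of the chain undefined.

Noise is i.i.d. Gaussian with equal variance in both series; the default
level is set so the baseline nulled gray-matter tSNR is 15 (VASO-like).
Scanner-specific noise structure (physiological fluctuations, drift, k-space
effects, inflow/T1 relaxation physics) is out of scope. Rigid motion is
generated as a smooth random-walk *trace only*: the images themselves stay
aligned, because registration belongs to external tools; the trace feeds the
framewise-displacement QC and nothing else.

### Default compartment parameters

`default_compartment_params()` encodes the phenomenology the pipeline is
meant to resolve, chosen once as plausible values for 7 T visual-cortex
responses:

* gray-matter CBV: slow kernels (mean 5.5/6.0/6.5 s for deep/middle/
  superficial, sd 3 s, 0.5 s delay), amplitudes 1.2/2.0/1.6 % with the
  middle layers strongest, no saturation — GM responses keep growing with
  stimulus duration. The slightly later superficial kernel produces the
  deep-to-superficial peak-latency gradient for short stimuli.
* vessel CBV: fast kernel (mean 2.5 s, sd 1.25 s), amplitude 2.2 %, with
  `cap` fixed to the peak of the 2 s boxcar convolution, so stimuli of 2 s
  and longer all produce the same saturated vessel peak.
* BOLD: vessel-dominated (5 % versus 1.0–2.0 % in GM, increasing toward the
  surface as a draining-vein gradient), kernels of mean 5–5.5 s, no cap.

With these defaults the vessel/GM peak-ratio of the VASO contrast is above 1
for 1 s stimuli, falls monotonically with duration, and drops below 1 by
24 s, while the BOLD ratio stays roughly constant — the qualitative pattern
the metrics module is designed to quantify. The acceptance checks compare
recovered quantities against the simulator's own recorded ground truth, not
against any empirical response amplitudes.

## Preprocessing

* **Framewise displacement** is the sum of absolute translation differences
  plus rotation differences converted to arc length on a 50 mm head radius
  (the customary radius for this metric; it is a parameter). Volumes are
  flagged when FD exceeds the nominal 0.9 mm voxel size.
* **Run averaging** is the voxelwise arithmetic mean of runs with identical
  grids, lengths and timing.
* **Temporal upsampling** by the jitter factor (4) uses linear
  interpolation, with original samples preserved at stride 4 and edge-hold
  beyond the last volume. Linear interpolation is monotone, artifact-free
  and exactly testable; the kernel is a configuration switch in the sense
  that the operation is a separate function, but no other kernel is
  currently implemented. Each upsampled series carries a `measured` flag
  marking which samples are original volumes.
* **BOLD correction (`boco`)** divides the nulled by the BOLD series
  voxelwise. If the BOLD series is one volume short, its first volume is
  duplicated. Voxels whose BOLD magnitude falls below `1e-6` times their
  temporal mean magnitude become `NaN` rather than infinities. The
  pipeline driver (`boco_run()`) divides the *native-rate* volume pairs and
  upsamples the corrected VASO series afterwards: dividing measured pairs
  before any interpolation keeps the correction a ratio of measurements and
  is exact under the cycle-wise contamination model, whereas dividing two
  independently interpolated series would reintroduce a first-order phase
  residual. `boco()` itself accepts series at any common rate.
* **tSNR** and the **1/CV T1-weighted map** are the temporal mean over sd of
  one series, respectively of the concatenated nulled+BOLD series, with
  zero-variance voxels flagged `NaN`.

## Equivolume layering

Cortical depth is computed from the label volume alone. The equidistant
depth of a GM voxel is `alpha = d_wm / (d_wm + d_csf)` from its distances to
the WM and CSF boundaries. The equivolume depth corrects `alpha` for
curvature so that equal depth increments enclose equal local volume: along a
cortical column the streamline cross-section scales as
`1 + K_w * alpha * T` (thickness `T`, WM-boundary curvature `K_w`), giving
the closed-form volume fraction

    depth = (alpha + K_w * T * alpha^2 / 2) / (1 + K_w * T / 2).

This reproduces the equivolume principle exactly for flat slabs (where it
reduces to the equidistant depth) and for cylindrically curved ribbons such
as the annulus validation geometry, whose analytic depth is
`(r^2 - r_in^2) / (r_out^2 - r_in^2)`; for doubly curved surfaces it is
first-order in the Gaussian-curvature term, which is adequate for the
smooth synthetic ribbons the package targets.

Numerical implementation: distances are *signed sub-voxel boundary
distances* (center-to-center distances to the nearest boundary-set voxel,
shifted by half a voxel, negative inside), smoothed by three passes of a
separable 3x3x3 box filter — the signed field is linear across each
interface, so the smoothing is unbiased there while it strips the lattice
noise of nearest-voxel distances. The level-set curvature is the divergence
of the normalized gradient of `d_wm - d_csf`, propagated to the WM boundary
via `K / (1 - K * d_wm)` (exact for cylinders) and averaged over the
dilated GM ribbon with ten box passes, since curvature varies slowly along
the ribbon while per-voxel differentiation of a discrete field is noisy.
These smoothing depths were fixed by validating against the annulus closed
form; on the default 40x40x10 annulus the maximum absolute depth error the
test suite asserts is 0.02. GM voxels with no reachable boundary would get
no depth (`NA`); layer binning uses equal-width depth bins with layer 1
deepest, 3 layers for temporal analyses and 11 for profiles. Anatomical
upsampling before layering (used on real data at sub-voxel resolutions) is
unnecessary on the synthetic grids and not applied.

The disc ROI grows geodesically from a center column: shortest paths on the
26-connected GM graph, each step weighted by its component tangential to
the local depth gradient, so travel along a column is free and the disc
spans all depths. This replaces a full (U,V) cortical parametrization,
which would be over-engineered for smooth synthetic ribbons.

## Event-related averaging

The chain follows a fixed order per voxel set (mask), layer and duration:

1. extract each trial from stimulus onset to the end of its rest period on
   the upsampled grid (trials cut short by the run end keep their available
   samples and are flagged);
2. average trials of the same duration across runs, interleaving jitters
   onto the 0.785 s grid;
3. divide by the baseline — the mean over the first and final 30 s of every
   run — and multiply by 100;
4. invert the sign for VASO, so CBV increases plot upward;
5. subtract the offset between the last short-ITI-covered timepoint and the
   first long-only timepoint from the long-only segment (the junction pair
   then holds the same value, the literal stitching rule);
6. zero the first timepoint.

Step 2 by default averages only *measured* samples at each timepoint: the
four jitter phases tile the effective grid, so every post-onset timepoint is
covered by exactly one jitter's original volumes, and a noise-free smooth
response is reconstructed exactly (the per-timepoint measured count `n` is
reported, and timepoints with no measured coverage fall back to the
interpolated samples). Setting `use_measured = FALSE` reproduces the plain
average over the upsampled grid, which is smoother but carries the linear
interpolation bias of the 3.14 s volume spacing. Relative trial times are
snapped to exact multiples of the sampling interval before grouping, so
floating-point onset arithmetic cannot split grid timepoints.

Division by the baseline (rather than `(S - baseline)/baseline`) follows
the literal step-3/4 wording; the two readings differ by a constant 100
that the final zeroing removes, so the choice has no observable effect.

## GLM

The hemodynamic regressor kernel is the moment-matched gamma density with
mean lag 6 s and sd 3 s (shape 4, scale 1.5, mode 4.5 s), sampled at a fine
grid and normalized to unit area. Each stimulus duration gets one regressor:
its boxcar train convolved with the kernel, sampled at the volume times.
High-pass filtering enters as discrete-cosine drift columns with
`K = floor(2 * T_run * 0.01 Hz)` — drifts with period above 100 s — rather
than as a separate filtering pass; this keeps the model linear, the columns
orthogonal, and the count exactly testable. Fitting is ordinary least
squares per voxel; contrast t-statistics are converted to z-scores by
matching tail probabilities at the residual degrees of freedom (computed on
the log scale). No prewhitening, spatial smoothing, or cluster inference is
applied. The GLM runs at the native volume rate per contrast; only the
event-related analysis uses the upsampled grid. Session-level z-maps are
combined by Stouffer's fixed-effects rule `sum(z)/sqrt(k)`, a deliberate,
labelled choice where a mixed-effects model would need more sessions than
the design provides. Depth profiles are layer-bin means of a statistic map
within an ROI, optionally min-max normalised per duration to compare
shapes.

## Time-to-peak and peak ratios

TTP is defined on the zeroed event-related average as the time of the
highest signal change between the initial deflection above zero and the
subsequent fall below zero, with the end of the extracted window acting as
the fall-off when the signal never crosses down. Two numerical guards make
the literal rule robust:

* crossings are detected against a threshold of 1 % of the series maximum,
  because an averaged, stitched curve can wiggle around zero at numerically
  tiny amplitude before the true deflection, which would otherwise truncate
  the span at its first sample;
* argmax ties are detected at a relative tolerance of `1e-6` and broken to
  the *earliest* sample. A saturated vessel response is exactly flat on its
  plateau up to previous-trial carryover of order `1e-5`, so exact-argmax
  would land arbitrarily within the plateau. The tie rule is a design
  decision; earliest-sample matches the "initial" reading of the
  definition and the generator's own convention.

The vessel/GM ratio divides the peak values found by the same span rule on
the two masks' averages, per duration; a non-positive GM peak invalidates
the ratio.

## Problem sizes and test scope

The simulator defaults (40x40x10 voxels at a nominal 0.9 mm, four vessel
tubes, tSNR 15) keep a four-run noise-free participant — simulation,
correction, averaging and metrics — around half a minute on one core, which
is the problem size the recovery tests use. Unit tests run on a smaller
24x24x4 ribbon. The test suite asserts, among others: exact BOCO inversion
(`< 1e-10`) and exact noise-free event-related recovery (`< 0.05`
percentage points); equivolume depth within 0.02 of the annulus closed
form; TTP recovery within one effective sample (0.785 s) and the monotone
duration-dependence of the VASO vessel/GM ratio; GLM null calibration
(`P(|z| > 1.96) = 0.05 ± 0.01` over 6000 voxels); and oracle equivalence of
trial averaging, OLS and the TTP scan against independent brute-force
implementations on randomized instances.

What passing these tests shows is that the *analysis chain* inverts the
*stated generative model*. Real data differ in ways the generator does not
emulate: registration errors and their interpolation, physiological and
thermal noise structure, inflow and CSF-volume effects on the nulled
signal, partial-volume mixing at 0.9 mm, vessel geometries more complex
than tubes, and between-session variability. Conclusions about those
effects require real data; the package's claim is correctness of the
machinery, not of the physiology defaults.

## Known limitations

* The equivolume correction is first-order in curvature off the validated
  slab/cylinder geometries; strongly folded or thin (< 4 voxel) ribbons
  will be less accurate.
* The quasi-static per-cycle contamination model removes a genuine (small)
  nulled-vs-BOLD timing asymmetry from the simulation; pipelines will see
  slightly cleaner corrections than on real data.
* Second-level combination is fixed-effects only; no across-participant
  inference is implemented.
* The division guard flags dead voxels but does not impute them; masks with
  many invalid voxels shrink the averaged sample silently (the per-timepoint
  `n` column is the audit trail).
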