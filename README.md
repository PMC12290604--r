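# vasodyn

Laminar VASO/BOLD hemodynamic-response analysis with a generative
layered-cortex simulator.

## The problem

Cerebral-blood-volume (CBV) weighted fMRI with slice-selective slab-inversion
VASO promises laminar specificity that gradient-echo BOLD cannot deliver,
because BOLD is biased toward draining veins at the cortical surface. But
interpreting depth-dependent CBV responses requires knowing how the response
depends on stimulus duration and on the vascular compartment: capillaries in
gray matter dilate slowly and keep responding as stimulation lengthens, while
macrovessels above the cortex react fast and saturate within a few seconds.
`vasodyn` implements the full analysis chain for a *symmetric* VASO
acquisition — one blood-nulled and one BOLD volume per 3.14 s cycle, built
from four equally spaced 0.785 s blocks — in which stimulus onsets are
systematically jittered over four cycle phases, so that event-related
averaging recovers responses at an effective resolution of 0.785 s.

The package is aimed at laminar-fMRI methodologists: every stage of the
pipeline is paired with a generative simulator of interleaved nulled/BOLD
time series over a synthetic cortical ribbon, with recorded ground truth, so
the whole chain is testable without scanner data.

## What it computes

* **Simulator** — annulus cortical ribbon (WM/GM/CSF labels plus
  vessel-dominated voxel tubes), jittered stimulus designs (durations 1, 2,
  4, 12, 24 s; short ITIs 10/12/14/20/24 s or long ITIs 20/22/24/30/40 s),
  and voxelwise signals
  `S_bold = S0_b (1 + delta(t))`,
  `S_nulled = S0_n (1 - v(t)) (1 + g * delta(t))`,
  where each compartment's `v` (CBV) and `delta` (BOLD) responses are
  saturating boxcar x gamma-variate convolutions and `g` is the
  BOLD-contamination gain.
* **Preprocessing** — framewise displacement (Power-style, 50 mm rotation
  radius) and high-motion flagging at the 0.9 mm voxel size; run averaging;
  4x temporal upsampling; BOLD-contamination correction by dynamic division
  (`boco`), with the first-BOLD-volume duplication rule and a division
  guard; tSNR and 1/CV T1-weighted maps.
* **Layering** — equivolume (or equidistant) cortical depth over the GM
  ribbon, binned into 3 or 11 layers; geodesic disc ROIs spanning all
  depths.
* **Event-related averaging** — per-trial extraction from onset to the end
  of the rest period, jitter-interleaved averaging per duration with
  per-timepoint sample counts, 30 s run-edge baselines, % signal change with
  VASO sign inversion, short/long-ITI offset stitching, first-timepoint
  zeroing.
* **GLM** — per-duration regressors from a gamma HRF (mean lag 6 s, sd 3 s)
  with discrete-cosine high-pass drift (0.01 Hz), voxelwise OLS with
  t-to-z conversion, Stouffer combination across sessions, depth profiles
  with min-max normalisation.
* **Metrics** — time-to-peak of each event-related average within its
  above-zero span, and the vessel/gray-matter peak-signal ratio per
  stimulus duration.

## Worked example

Simulate a small noise-free participant (two runs, one per ITI class), run
QC, and recover the headline statistics:

```r
library(vasodyn)

geo   <- build_geometry(grid_shape = c(24, 24, 4), annulus_radii = c(5, 9),
                        n_vessels = 2, seed = 1)
acq   <- acq_scheme()                      # 4 x 0.785 s blocks, 4 jitters
model <- compartment_model(noise_sd = 0)   # noise-free recovery demo
sim   <- simulate_participant(geo, acq, model, n_short = 1, n_long = 1,
                              seed = 7, noise = FALSE)

fd <- framewise_displacement(sim$runs[[1]]$motion)
cat("volumes with FD > 0.9 mm:", length(flag_high_motion(fd, 0.9)), "\n")
#> volumes with FD > 0.9 mm: 0

pm <- participant_metrics(sim)
pm$ttp[pm$ttp$contrast == "vaso" & pm$ttp$compartment == "vessel",
       c("duration_s", "ttp_s", "peak_value_pct")]
#>   duration_s ttp_s peak_value_pct
#> 1          1  3.14          0.748
#> 2          2  3.93          1.319
#> 3          4  3.93          1.381
#> 4         12  3.93          1.381
#> 5         24  3.93          1.381

pm$ratio[pm$ratio$contrast == "vaso", c("duration_s", "ratio")]
#>   duration_s ratio
#> 1          1 3.510
#> 2          2 2.912
#> 3          4 1.636
#> 4         12 0.903
#> 5         24 0.873
```

The vessel CBV response peaks early (~3–4 s) and its amplitude plateaus at
1.381 % from 2 s of stimulation onward — the saturation built into the
generator and recovered by the pipeline. Gray matter keeps growing with
duration, so the vessel/GM peak ratio falls monotonically and crosses 1
between 4 s and 12 s: short stimuli weight the VASO signal toward
macrovessels, long stimuli toward the microvasculature.

`plot_era()`, `plot_layer_profile()` and `plot_fd()` draw the corresponding
ggplot figures; `write_simulation()` / `simulate_from_config()` exchange
NIfTI volumes, BIDS-style events TSVs, motion TSVs and ground-truth JSON.

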