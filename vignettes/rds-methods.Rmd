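---
title: "Models and methods: radial direction selectivity in bipolar cells"
author: "rdsbc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: radial direction selectivity in bipolar cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(rdsbc)
```

## The scientific problem

Retinal bipolar cells (BCs) relay photoreceptor signals to the inner
retina. Their receptive fields (RFs) combine an excitatory centre with a
delayed, antagonistic surround. When a bright object *originates* over the
RF centre and moves outward, the centre is driven before the surround's
suppression arrives; when the object *terminates* on the centre after
crossing the surround, the delayed suppression lands on top of the centre
response. The result is *radial direction selectivity* (rDS): a preference
for motion away from the RF centre, formally analogous to a Barlow–Levick
detector built from the centre–surround geometry itself. Downstream,
starburst amacrine cells (SACs) prefer centrifugal motion along each
dendrite; a ball-and-stick dendrite model driven by BC inputs lets one ask
how much of that preference BC rDS alone can supply.

This package implements the full computational chain at desk scale: 1-D
space-time stimuli; a synthetic-data generator for centre-surround RFs and
noisy response traces (in place of two-photon glutamate imaging);
Gaussian-process response smoothing and the d′ statistic; penalised-spline
RF estimation and feature extraction; sparse-PCA + Gaussian-mixture RF
clustering with BIC model selection; linear-convolution motion-response
prediction with preference and motion-coherence indices; and a
multicompartment SAC dendrite simulation with Ca²⁺ dynamics and a
direction-selectivity index (DSI).

## Stimuli

All stimuli are 1-D contrast fields over (space, time) with background 0
and values in [−1, 1] (`spacetime_stim`). Heights of the physical bars
never enter any computation, so the second spatial dimension is dropped.
Rasterisation is centre-sampled: a bin is lit when its centre lies under
the bar, with no anti-aliasing — this matches a discrete projector raster
and keeps frame-level oracles exact. Conventions: space bin centres at
`origin_um + i*dx`, time bins `[t, t+dt)` sampled at mid-bin; defaults
`dx` = 1 µm and `dt` = 1 ms for motion stimuli, one bin per bar and per
noise frame for the 20 Hz binary-noise stimulus.

The looming stimulus applies its rate (default 800 µm/s) to the spot
*diameter*, so each edge moves at half that rate; the alternative
radius-rate convention is available via `rate_on = "radius"`. A receding
stimulus is exactly the time reverse of the loom.

The motion-coherence index of a bar sequence with positions $x_i$
presented in temporal order is

$$k = \frac{\sum |x_j - x_i| - s_{max}}{s_{min} - s_{max}},$$

where the sum runs over temporally adjacent bar pairs and $s_{min}$,
$s_{max}$ are the extreme adjacent-distance sums over *all* orderings of
the same positions, found by exhaustive enumeration (5040 orderings for 7
bars; supported to n = 8). Perfect apparent motion has $k = 1$, the
maximally scrambled ordering $k = 0$. For n = 2 every ordering is
equivalent and the index is defined as 1. The index is invariant under
time reversal, so it measures coherence, not direction.

## The synthetic RF generator

`make_rf()` builds RFs as

$$W(x, \tau) = g_c(x)\,k_c(\tau) - s_{\mathrm{eff}}\,g_s(x)\,k_s(\tau),$$

with concentric spatial Gaussians ($\sigma_s > \sigma_c$) and
raised-cosine temporal kernels: a biphasic centre (main lobe peaking at
`center_tau_s`, rebound lobe weighted by `biphasic_weight`) and a delayed
monophasic surround peaking `surround_latency_s` later. Raised-cosine
bumps were chosen over gamma kernels because their compact support makes
the generator's parameters exactly recoverable by the region-based feature
extractor on noise-free RFs: at the centre-peak time the surround kernel
is still zero (for latencies at least as long as the surround half-width),
so the planted FWHM and latency survive extraction exactly, and
`surround_strength` is *defined operationally* as the surround's peak
amplitude in the flank region (beyond 1.5 centre FWHM) relative to the
centre peak — the quantity the extractor measures. With
`surround_strength = 0` the RF is exactly rank-1 (space–time separable);
any positive latency makes it non-separable.

Trace noise is additive Gaussian (`simulate_response`), not Poisson,
because fluorescent glutamate-sensor signals are analog photometry, and
every stochastic step takes an explicit seed with no global RNG state.

Two default parameter sets encode the study conditions:

* `default_param_ranges()` for populations used in estimation/clustering
  recovery: centre σ 15–30 µm, surround 60–100 µm, surround strength
  0.2–0.8, centre time-to-peak 40–80 ms, latency 40–80 ms.
* `default_cluster_rfs()`: five On "cluster" RFs for the motion-model
  ensemble analyses, with slower kernels (time-to-peak 80–120 ms, the
  regime of glutamate-sensor kernels estimated from 20 Hz noise) and weak
  *measured* surrounds (0.15–0.35) — noise mapping with small
  high-contrast bars systematically underestimates surround strength, so
  measured cluster surrounds sit well below the values used for the
  surround-manipulation experiments.

What the generator deliberately does **not** emulate: imaging point-spread
functions, photobleaching, pixel-level movie noise, ROI segmentation, or
output nonlinearities of glutamate release. Tests passing on this
generator therefore certify the algorithmic chain, not robustness to every
property of real recordings.

## Trace processing, GP smoothing and d′

`preprocess()` applies a 5th-order Butterworth high-pass at 0.2 Hz
(zero-phase, forward–backward) and z-normalises. `smooth_response()` fits
an exact Gaussian-process regression with an RBF kernel (variance 1.1,
lengthscale 0.05 s) to all trials of each condition and evaluates the
posterior mean and s.d. on a 50 Hz grid, refined to 125 Hz inside an
optional warp window covering the moving-bar epoch. An exact GP is used
rather than a sparse approximation because desk-scale trial sets are
small; the lengthscale is interpreted in seconds. The observation-noise
variance is estimated from between-trial variance when several trials are
available. Response sets whose posterior-mean s.d. stays below 0.1 for
every condition are flagged non-responsive and discarded.

The motion-preference statistic between two conditions is

$$d' = \frac{\mu_1 - \mu_2}{\sqrt{0.5(\sigma_1^2 + \sigma_2^2)}},$$

where $\mu_i$ is the *signed* peak of the posterior mean inside the bar
window and $\sigma_i$ the posterior s.d. of the mean at that peak (the
posterior-sd-of-the-mean reading of "the s.d. at this peak"; the
predictive s.d. is available by adding the noise variance in the smoother
configuration). d′ is antisymmetric and invariant to common rescaling of
both responses.

## RF estimation and features

`estimate_rf()` performs regularised reverse correlation: the response is
regressed on the stimulus history expanded on a tensor-product cubic
B-spline basis over (space, lag 0–0.5 s), with second-difference roughness
penalties along both axes plus a small ridge (so the fit shrinks to zero,
not to the bilinear nullspace, as the penalty grows). The penalty weight
is selected by generalised cross-validation by default. The basis sizes
(16 space × 12 lag) are not critical; the recovery tests — median
truth-correlation ≥ 0.8 at SNR 3, ≥ 0.95 noise-free — define adequacy.
The estimator is linear in the response at fixed penalty.

`extract_features()` measures, on the polarity-corrected RF: (i) latency =
surround-peak time − centre-peak time; (ii) surround strength =
surround/centre peak ratio; (iii) biphasic index = |max/min| of the centre
temporal kernel; (iv) centre FWHM from a log-quadratic Gaussian fit to the
spatial profile at the centre-peak time. The default regions are centre
within 1 FWHM and flanks beyond 1.5 FWHM (the analysis that motivated
them fixed the regions by eye; both are parameters here). Because the
concentric surround overlaps the centre bin, the centre-bin trace carries
the surround dip; the extractor removes it by subtracting the flank-kernel
shape scaled to the centre-bin value at the surround-peak time. This is
exact when the centre kernel has decayed by that time and approximate
(biphasic index biased up) when the centre rebound overlaps the surround
peak — latency, strength and FWHM are unaffected. Peak times and positions
use parabolic sub-bin interpolation.

`rf_trajectory()` implements the space-time trajectory measure used for
SAC RFs: the spatial peak is located in an early and a late lag window and
the displacement $x_2 - x_1$ and slope $(x_2-x_1)/(t_2-t_1)$ are returned
in stimulus time.

## Clustering

`align_centers()` pre-clusters RFs hierarchically (correlation distance,
average linkage — the criterion value 0.05 is fixed by the original
analysis, the metric/linkage are this package's choice and configurable),
takes the extremum of each pre-cluster mean as the centre, and shifts each
member by whole bins (plus a per-member cross-correlation refinement) onto
a common reference bin. `crop_half()` flattens the centre-to-edge half of
the aligned RF — clustering on half the RF mirrors the half-RF analysis
forced by possible stimulus offsets. `fit_cluster_model()` reduces the
vectors to 4 sparse principal components (an in-package rank-one penalised
matrix decomposition with L1 soft-thresholding and deflation, equal to the
SVD at penalty 0), optionally appends the standardised IPL depth so no
feature dominates, and fits Gaussian mixtures for each candidate cluster
count (default 3–19), selecting the count that minimises BIC. Mixtures use
full covariances by default and the deterministic model-based hierarchical
initialisation of the mclust implementation, so refits on the same data
are bit-identical. `predict_cluster()` carries maximum-posterior labels to
new data (e.g. drug conditions) through the same projection and scaling.
`stratification_profile()`/`stratification_correlation()` compare cluster
depth densities (Gaussian KDE on [0, 1]) against reference (EM-derived)
profiles with Pearson correlation and a 0.7 match threshold.

## The linear motion model

`conv_predict()` convolves each spatial bin's lag kernel with the
stimulus time course at the same physical location and sums over space —
a pure linear model with no output nonlinearity (rectification exists only
in the SAC input pathway). Stimuli are zero-padded before onset; use
`pad_stimulus(after_s = lag_span)` so delayed responses to the final
frames play out. Grids are aligned by physical coordinates, with
sum-preserving linear resampling when resolutions differ.

`preference_index()` is $(p_1 - p_2)/(p_1 + p_2)$ on signed temporal
peaks. `rds_tuning()` builds stimulus pairs anchored to the RF centre.
The originate/terminate pair is constructed as exact time reverses of one
another over the same region — the originating bar body appears with its
trailing edge at the centre and moves outward; the terminating bar arrives
from the surround and stops there. Under this convention a surround-free
RF with a temporally symmetric kernel has *exactly* zero preference, which
pins the rDS signal on centre–surround structure. With a biphasic centre
kernel a small onset-transient preference remains even without a surround;
the same onset transient makes the loom/recede preference sensitive to how
the first frame of the receding stimulus is treated (a full-field onset),
so no sign claim is made for that pairing on synthetic RFs.

At low velocities the terminating response of a strongly surround-
suppressed RF is clipped at zero peak and the preference saturates at 1;
the velocity-averaged preference over 500/1000/2000 µm/s is therefore used
as the population rDS score. Across graded synthetic populations this
score *increases with surround strength and decreases with latency* —
reproducing the signs of the reported rank correlations (+0.72 and −0.89).

`scale_surround()` multiplies opposite-polarity values in the surround
region (default: beyond one centre FWHM) by a scalar, leaving the centre
untouched; `decompose_center_surround()` splits the prediction into centre
and surround contributions, which sum exactly to the full prediction by
linearity.

## The SAC dendrite model

`sac_config()` carries the biophysical constants: axial resistivity
150 Ω·cm, membrane resistivity 21 700 Ω·cm², capacitance 1 µF/cm², leak
reversal −54.4 mV, Ca reversal 120 mV, peak Ca conductance 0.013 mS/mm²
(distal third only), resting Ca 50 nM, Ca decay 5 ms, influx conversion
20 M/nC, step 0.1 ms; geometry: iso-potential 7 µm soma, 150 µm dendrite
(0.4 µm diameter for the first 10 µm, 0.2 µm beyond), discretised into
150 one-µm compartments (the compartment count is a package choice;
halving the step and doubling the compartments moves the peak distal
voltage by under 1%). The Ca-channel gating kinetics are not specified by
the source analysis: the package uses gate = m², with a Boltzmann
steady-state (half-activation −30 mV, slope 6 mV) and a 1 ms gating time
constant, all flagged as package defaults in the configuration — DSI is
computed from voltage, so no headline quantity depends on them.

Integration is backward-Euler on the passive cable (the stiff part: the
axial-to-capacitive rate ratio is ~3×10⁵ per step), with the Ca current
evaluated explicitly (its conductance is slow and small relative to the
step) and exponential updates for the gate and the Ca concentration. The
implicit operator is constant, so it is factorised once per simulation.
γ_Ca is applied to the compartment membrane Ca current directly
(d[Ca]/dt = −γ I_Ca − ([Ca]−Ca₀)/τ), the per-volume normalisation being
absorbed into the printed constant. The drive is injected as *current* at
the mapped synapse positions. The soma is a sealed end (no load from
unmodelled dendrites).

Bipolar input (`bc_drive`): each synapse sees the stimulus through its
type's conditioned RF centred at its own dendritic position; the drive is
`scale · n_syn · max(0, baseline + prediction)`, with a spontaneous
baseline of 10% of the synapse's peak prediction (the baseline level is
not specified by the source; it is configurable) — stimulation of the
centre raises the drive, surround stimulation can push it below zero
where rectification clips it. RF conditioning (`condition_rf`) follows the
SVD route: top-3 components, spatial/temporal vectors linearly
interpolated 20×/1.6×, reconstruction, then mirroring of the
centre-to-edge half into a fully symmetric spatial RF. The synapse map
places 2 synapses per 10 µm segment by default (the anatomical density
profile is user-configurable), wires a proximal type below 50 µm and a
distal type beyond (both labels configurable), and supports the wiring
manipulations `all_proximal`, `all_distal` and `swapped`, all conserving
the total synapse count. The default input set pairs a sustained,
weak-surround proximal type with a transient, strong-surround (rDS)
distal type, for On or Off pathways.

`calibrate_scale()` bisects the drive scale (log grid) until the peak
depolarisation of the most distal compartment reaches −35 ± 0.5 mV at the
lowest velocity. `sac_dsi()` measures, per distal-third compartment, the
peak depolarisation above the pre-stimulus resting level (a time-integral
measure is selectable) and averages (CF − CP)/(CF + CP) over those
compartments. `run_protocol()` ties it together: CF is soma→tip motion;
the CP stimulus is the exact spatial mirror of the CF stimulus about the
path midpoint, so a wiring-symmetric model with identical surround-free
inputs yields |DSI| < 0.05 (not exactly zero: a soma-loaded cable read
out at its distal end retains a small Rall-type sequence asymmetry). Paths:
`single_dendrite` (0–150 µm), `cell_diameter` (150 µm extension on the
soma side), `cell_surround` (100 µm extension beyond the tip). On the
default synthetic set the model prefers centrifugal motion across the
protocol velocities, most strongly at the slowest (250 µm/s) where the
centre–surround delay is engaged — at 500–1000 µm/s the preference stays
positive but small. Near-abolishing the surround (factor 0.01) collapses
the slow-velocity selectivity, the cell-surround path (which lets the bar
cross the full distal surround) strengthens it, and the On-model
cell-diameter path inverts the DSI sign at high velocity.

## Numerical choices and degenerate inputs

* Exhaustive coherence search is limited to 8 bars; beyond that the
  package raises an error rather than approximating.
* Peak finding uses parabolic interpolation around the discrete argmax;
  ties resolve to the first index.
* All-identical cluster vectors short-circuit to a single cluster at the
  minimum candidate count (a Gaussian mixture on zero-variance data is
  singular); candidate counts exceeding the sample size are skipped with
  a warning.
* Degenerate traces (zero variance), empty conditions, flat RFs in a
  trajectory window, non-bracketing calibration ranges and non-finite
  voltages all raise typed, descriptive errors.
* Problem sizes in the tests — 100–150 s of 20 Hz noise for recovery,
  populations of tens of ROIs, 20 seeded clustering runs, SAC protocols
  at 2–3 velocities — were chosen as the smallest sizes at which the
  statistical criteria are stable.

## Known limitations

* Stimuli and RFs are 1-D in space; no chromatic or 2-D structure.
* The convolution model is purely linear; gap junctions and nonlinear
  subunits are out of scope.
* The loom/recede preference of synthetic RFs is onset-transient
  dominated and no sign-level claim is made for it.
* The SAC model omits inhibitory inputs, voltage-gated channels other
  than the distal Ca current, and the full radial morphology; DSI
  magnitudes (not signs) depend on the unspecified baseline level and
  gating constants.
* Measured-vs-planted biphasic indices are biased when the centre rebound
  overlaps the surround peak (see RF features above).
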