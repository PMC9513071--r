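# rdsbc — radial direction selectivity of retinal bipolar cells

Retinal bipolar cells (BCs) have centre–surround space-time receptive
fields (RFs): an excitatory centre and a wider, delayed, antagonistic
surround. That geometry alone makes a Barlow–Levick-style motion detector:
a bright object *originating* over the RF centre and moving outward drives
the centre before the delayed suppression arrives, while an object
arriving from the surround is met by suppression — *radial direction
selectivity* (rDS). `rdsbc` is an R package for studying this computation
end-to-end at desk scale, for retinal physiologists and modellers:

* **Stimuli** — 1-D moving bars, 20 Hz binary noise, looming/receding
  spots, apparent-motion and random bar sequences, with the
  motion-coherence index
  *k* = (Σ|x_j − x_i| − s_max)/(s_min − s_max) ∈ [0, 1]
  (s_min/s_max by exhaustive search over orderings).
* **Synthetic data** — ground-truth difference-of-Gaussians space-time
  RFs with biphasic centres and delayed surrounds, populations with
  type labels, and noisy response traces (the package's stand-in for
  two-photon glutamate imaging).
* **Responses** — Butterworth high-pass + z-scoring, Gaussian-process
  smoothing (RBF kernel, posterior mean ± s.d. on a 50/125 Hz grid), and
  the motion-preference statistic
  d′ = (μ₁ − μ₂)/√(0.5(σ₁² + σ₂²)).
* **RF estimation** — penalised tensor-spline reverse correlation over a
  0.5 s lag span, plus feature extraction (centre–surround latency,
  surround strength, biphasic index, centre FWHM) and the RF-trajectory
  velocity measure.
* **Clustering** — centre alignment, half-RF flattening, sparse PCA,
  Gaussian-mixture clustering with BIC model selection, and
  stratification-profile correlation against anatomical BC types.
* **Motion model** — linear convolution predictions, preference index
  (p₁ − p₂)/(p₁ + p₂), velocity tuning, surround scaling,
  centre/surround decomposition, coherence scans.
* **SAC model** — a biophysical ball-and-stick starburst amacrine cell
  dendrite (150 µm, iso-potential soma, distal Ca²⁺ channels and
  first-order Ca²⁺ dynamics) driven by RF-based BC inputs, with the
  direction-selectivity index DSI = (CF − CP)/(CF + CP) along the distal
  dendrite, wiring manipulations and motion-path variants.

## Worked example

```r
library(rdsbc)

# a radially direction-selective synthetic RF
rf <- make_rf(syn_rf_params(surround_strength = 0.5,
                            surround_latency_s = 0.06),
              dx = 10, dt = 0.01)
extract_features(rf)
#>    latency_s surround_strength biphasic_index fwhm_um
#> 1 0.06040203         0.5024449        5.22872 47.0964

# originating vs terminating motion preference across velocities
rds_tuning(rf, c(250, 500, 1000, 2000))
#>   velocity_um_s preference                pairing
#> 1           250  1.0000000 originate_vs_terminate
#> 2           500  1.0000000 originate_vs_terminate
#> 3          1000  0.9999998 originate_vs_terminate
#> 4          2000  0.1236984 originate_vs_terminate

# SAC dendrite: centrifugal vs centripetal moving bar
pr <- run_protocol(sac_config(), velocities = c(250, 500, 1000))
pr
#>   velocity_um_s         dsi
#> 1           250 0.092106841
#> 2           500 0.001753819
#> 3          1000 0.002401019
```

The tuning preference is (peak_originating − peak_terminating) /
(peak_originating + peak_terminating): 1 means the terminating response is
fully suppressed (its peak is clipped at zero by the delayed surround),
and the preference relaxes at high velocity where the bar outruns the
suppression. The SAC DSI is positive at every velocity: the model dendrite
prefers centrifugal (soma→tip) motion, most strongly at the slowest
velocity where the centre–surround delay of its bipolar-cell inputs is
engaged.

`run_pipeline()` chains all stages on synthetic data (population →
responses → RF estimation → clustering → motion model → SAC protocol) and
writes CSV artifacts plus a manifest with checksums; rerunning the same
config reproduces identical checksums.

See `vignette("rds-methods")` for the models, parameter meanings, design
choices and limitations.

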