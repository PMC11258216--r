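# spectralmct

Analysis toolkit for multi-energy-bin (spectral) photon-counting micro-CT
volumes of contrast-enhanced small animals, for preclinical imaging groups
working with K-edge contrast agents.

Photon-counting detectors sort photons into energy bins, so one scan yields
several co-registered volumes of linear attenuation coefficients (cm⁻¹).
Under the five-bin protocol (7,20), (20,30), (30,47), (47,73), >73 keV the
three middle bins form the analysis channels (I₁, I₂, I₃); the K-edges of
iodine (≈33 keV) and barium (≈37 keV) fall inside the third bin, so agent
content shows up as a characteristic cross-bin pattern. The package
provides:

* **Colorization** — a voxel's channel vector y = (I₁, I₂, I₃)ᵀ has a
  direction (color tone) that identifies the material independent of
  concentration. An invertible channel transform C magnifies tone
  differences before RGB display:

      I_R = 1.5 (I₁ − I₂),  I_G = 2.5 (I₂ − I₃),  I_B = 0.34 I₃

  with an alternate preset [1, 2, 0.3] for a second protocol. Invertibility
  keeps the material-to-tone mapping unique.
* **ROI metrics** — CNR = (x̄_tumor − x̄_muscle)/s_muscle and
  SNR = x̄_muscle/s_muscle per channel, plus a right-tailed Wilcoxon
  rank-sum test (exact by enumeration for small ROIs, normal approximation
  with tie/continuity corrections otherwise).
* **Mask refinement** — slicewise manual tumor outlines are smoothed by
  anisotropic Gaussian voting across slices and re-thresholded (majority
  vote at 0.5).
* **Paired discrimination** — per-tumor per-channel mean/std features, a
  one-sample Kolmogorov–Smirnov normality screen, the paired t-test
  t = D̄/(S_D/√n) ~ t_{n−1} (two-sided p via the regularized incomplete
  beta), and an exact convex-hull check of linear separability in the
  (mean, std) plane.
* **A spectral phantom simulator** — parametric photoelectric + Compton
  attenuation with multiplicative K-edge jumps, diffuse (small-molecule)
  vs punctate (nanoparticle vessel-dot) tumor enhancement regimes, and
  Gaussian reconstruction noise calibrated to a target background SNR —
  so the full pipeline runs and is validated without scan data.

Volumes are 4-D NIfTI (x, y, z, bin) plus a JSON sidecar (bin edges,
usable flags, voxel size, display orientation); masks are 3-D NIfTI.

## Worked example

```r
library(spectralmct)

ph  <- build_phantom(phantom_config(seed = 42))
met <- roi_metrics(ph$volume, ph$rois)
round(met$snr, 2)
#> 20.09 20.79 20.18
round(met$cnr, 2)
#>             channel1 channel2 channel3
#> tumor_left      1.65     4.42     1.98
#> tumor_right     1.59     2.77     1.79
```

The muscle-background SNR lands on the configured target of 20 in all three
channels. The diffuse iodine-regime tumor (`tumor_left`) shows its largest
CNR in channel 2 — the bin containing the K-edge — and channels 2–3 exceed
channel 1, the expected spectral signature of a K-edge agent; the punctate
nanoparticle-regime tumor has lower whole-tumor CNR because only vessel
dots are enhanced.

```r
co     <- build_cohort(cohort_spec(seed = 42))   # 6 mice, A vs B paired
report <- discrimination_report(cohort_features(co))
report
#> Paired discrimination of A vs B (n = 6 mice)
#>  channel feature   ks_p        t df      p_value reject
#>        2    mean 0.9596 7.972896  5 0.0005008111   TRUE
#>        2     std 0.9296 8.888760  5 0.0002998730   TRUE
#>  ... (channels 1 and 3 similar)
#> Strict (mean, std) linear separability per channel: yes, yes, yes
```

Model A has 8× the vessel-dot density of model B: the KS screen does not
reject normality of the paired differences (ks_p ≫ 0.05), the paired
t-tests reject equality of both mean and std at α = 0.05 in every channel,
and the two models' (mean, std) scatter points are strictly linearly
separable — the tumor models are discriminated from first-order statistics
alone.

A command-line front end (`inst/cli/spectralmct`) exposes the same stages:
`simulate`, `simulate-cohort`, `colorize`, `roi-metrics`, `refine-mask`,
`discriminate`, each writing a JSON provenance manifest.

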