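---
title: "Methods: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the quantifications it
implements for titin-cleavage experiments: what each model assumes,
which tunable parameters matter, what the synthetic-data generator does
and does not emulate, and where the design was genuinely open.

## 1. The fracture-area metric for Z-disk disorder

**Model.** Z-disks in longitudinal electron micrographs are thin, dark,
near-transverse lines. Disorder after titin cleavage manifests two ways:
each line becomes wavy, and lines tilt out of register with one another.
The metric captures both. Each segmented Z-disk path is fitted by
orthogonal (total-least-squares) regression — the first principal
direction of the coordinate scatter through the centroid — giving a mean
squared orthogonal residual `MSR_i` (nm²), an axial angle `θ_i`
(period 180°, measured from the image vertical) and a length `L_i`. With
`θ̄` the length-weighted axial circular mean (computed on doubled
angles, since lines are unoriented) and `Δθ_i = θ_i − θ̄` wrapped into
[−90°, 90°], the score is

```
FA = Σ L_i · MSR_i · (1 + |Δθ_i|/θ_ref) / Σ L_i      [nm²]
```

**Why this functional form.** The weight must (a) reduce to 1 when all
lines are parallel, so that the pure-residual score (and the zero law
for straight parallel lines) is preserved, (b) grow with angular
deviation, and (c) keep the output in nm². The affine form
`1 + |Δθ|/θ_ref` with `θ_ref = 45°` is the simplest weight with these
properties; it is a declared convention, configurable per call, because
the underlying EM software is described only as weighting residuals "by
the angular difference" without a formula. Weights multiply residuals,
so straight lines at differing angles still score 0 — angular spread
alone cannot create area.

**Orthogonal, not y-on-x, regression.** Z-disk lines are near-vertical;
ordinary regression of y on x is ill-conditioned there and its residuals
conflate with line orientation. TLS residuals are rotation-equivariant,
which the rotation-invariance property test exercises directly.

**Segmentation recipe** (the published description says only "various
filters"; this chain is the package's convention, validated by the
property suite):

1. invert and Gaussian-smooth (`sigma_px`, default 2 px);
2. ridge response = magnitude of the most negative eigenvalue of the
   local Hessian (line-like structures, not step edges, maximize it);
3. threshold at a quantile of the positive response (default 0.90);
4. thin to one ridge point per image row (row-wise response maxima);
5. **ridge-vs-edge test**: a candidate point is kept only if the
   smoothed image is darker at the point than at *both* horizontal
   flanks (default offset 120 nm). A-band borders and image-frame
   boundaries are steps — darker on one side only — and are rejected
   here, before linking, so they can never be chained into a path;
6. link points across adjacent rows into connected paths (greedy
   nearest-column linking, max jump 3 px);
7. sub-pixel localization: each point is refined by the vertex of a
   least-squares parabola fitted to the smoothed intensity sampled along
   the path's normal direction (±3 px). Sampling along the normal, not
   along the row, keeps localization unbiased for tilted ridges, which
   is what makes the 30°-rotation score agree within 10% and the nm²
   score agree within 5% when the pixel size is halved;
8. gates: path extent ≥ `min_length_nm` (default 500 nm) and axial
   orientation within ±30° of the dominant (length-weighted mean)
   orientation of the candidates. The dominant orientation is estimated
   from the candidate paths themselves rather than from the image power
   spectrum; on striated images the two estimates coincide, and the
   path-based one needs no second Fourier pass.

**Numerical floor.** Discretization and noise leave a residual score of
well under `0.5·(nm/px)²` on straight Z-disks (measured ~0.4 nm² at
8 nm/px); treat values at that scale as zero.

## 2. Synthetic data: the stated world

The study's raw images and traces are not deposited, so every stage is
validated against a generator whose ground truth is exact.

* **Micrographs**: Z-disks as dark bands (Gaussian cross-section, ~80 nm
  wide) following per-disk centerlines `x(y) = x₀ + tan(θ)·(y−ŷ) +
  w(y)`; A-bands as darker rectangles (1.6 µm default) centered between
  Z-disk pairs; Gaussian pixel noise, default SD 5% of the dynamic
  range. Waviness `w` is either a sinusoid (peak amplitude `A`, so the
  RMS about the fitted line is `A/√2` with integer periods) or a
  smoothed Gaussian random walk rescaled to a requested RMS. All random
  draws are made up front as standard deviates and *scaled* by the
  requested magnitudes, so scenes generated with the same seed but
  different waviness or jitter are matched — the monotonicity property
  tests compare like with like. Default pixel size 4 nm (typical EM
  scale; tests mostly use 8 nm for speed).
* **Particle fields**: Poisson label counts per half-sarcomere at the
  epitope offset ± placement noise, an optional recoiled fraction
  relocated to a Z-disk-proximal offset (bimodality), uniform background
  labels flagged in truth, and log-normal diameters (silver enhancement
  varies apparent size; the distribution family is a modeling choice).
* **Force traces**: a generalized Maxwell (standard-linear-solid family)
  model — parallel spring `k_el` plus arms `(k_m, τ)` — integrated
  piecewise-analytically under the piecewise-linear length input and
  sampled at 1000 Hz. The SLS is the minimal constitutive model with
  both velocity-insensitive and velocity-sensitive components; the
  experiments are described only at that phenomenological level. Total
  force is `(b + (1−b)·titin_fraction) · V(t)`: with full cleavage
  (`titin_fraction = 0`) the baseline fraction `b` of force remains,
  reflecting the observation that roughly half of passive elastic force
  survives complete titin cleavage.
* **Indentation curves**: exact Hertz force past a contact offset, flat
  baseline before it, truncated at the 3 nN trigger.
* **Gel lanes**: Gaussian bands with areas proportional to composition
  on a linear baseline.

What the generator does **not** emulate: membranes, mitochondria and
fixation artifacts in EM; antibody specificity; crossbridge kinetics;
gel smearing or molecular-weight calibration. A green recovery test
therefore establishes estimator correctness on idealized structure, not
robustness to every real-world artifact.

## 3. Estimator choices in fiber mechanics

* **Protocol segmentation** works on the SL channel: boxcar smoothing
  (window `smooth_s`) followed by a lagged central difference, with a
  two-level hysteresis threshold (open at 0.02 µm/s, close at half
  that). The lagged-difference slope estimator is what makes
  segmentation immune to SL channel noise — raw sample-to-sample
  derivatives at 1000 Hz amplify noise ~1000-fold.
* **Elastic tension** = mean force over the final 1 s of each 10 s hold;
  **viscous tension** = ramp-end peak minus elastic. The peak is taken
  on a lightly smoothed force (25 ms boxcar; the raw max of noisy
  samples is upward-biased) over the terminal 5% of the ramp extended
  0.25 s into the hold (so a blurred phase boundary cannot miss the true
  peak). Additivity (elastic + viscous = peak) holds by construction.
* **Timecourse normalization** divides by the time-matched control mean
  and then by the value at t = 0, exactly as the experiments do; no
  detrending is ever applied, so ordinary stress relaxation is removed
  only by the control division.
* **Active steady state** = mean over the final 10 s of the ~120 s
  activation, guarded by a terminal-slope plateau check.
* **Intact-titin covariate**: Wt = 1.0; Het post-protease = 0.5 and Hom
  post-protease = 0.0 by design; measured gel fractions may override.

## 4. Hertz fitting

`F = (4/3)(E/(1−ν²))√R δ^{3/2}` with ν = 0.5 (incompressible tissue;
configurable) and R = 5 µm (half the 10 µm bead). Given a contact point
the modulus has a closed-form least-squares solution, so the only
nonlinear step is contact detection: baseline statistics from the flat
segment, first sustained excursion above baseline + 5 SD, then a 1-D
search minimizing the `a·max(0, z−z₀)^{3/2}` fit error. The fit domain
is capped at δ ≤ 0.4 R (small-indentation validity; the experimental
~300–400 nm depths are far inside). Cantilever deflection correction
(δ = z − F/k_c, default k_c = 0.035 N/m when requested) is available but
off by default since synthetic curves are generated in true indentation
coordinates. Depth at the trigger force is interpolated on the measured
curve; when the curve stops just short of the trigger the fitted model
is inverted instead.

A note on the ~33% printed changes: on ideal Hertz curves at equal
trigger force, depth scales as `E^{−2/3}`, so the 4.81 → 3.24 kPa
modulus drop predicts a `(4.81/3.24)^{2/3} − 1 = 30.2%` depth increase,
slightly below the measured ~33%. The package reports both without
forcing agreement — the gap is a model-vs-measurement fact.

## 5. Gel densitometry

Baseline removal uses a morphological rolling-minimum opening (window
3× the widest band window) rather than polynomial fitting — robust to
the sloped backgrounds of agarose-strengthened gels and incapable of
cutting into broad bands. Percent cleaved = `100·AM/(AM + intact)`: the
T2/Cronos doublet is excluded from the denominator because it
co-migrates with unrelated species, and the Z-I fragment is not used
(co-migration risk). The MyHC/titin "titin" denominator defaults to
intact + A-M + Z-I, with the band set configurable since whether
T2/Cronos belongs there is not specified.

## 6. The centering force balance

First-order arithmetic: per-molecule force change `ΔF = F_ref·(d/d_ref)`
with 12 pN at 35 nm as the reference, six titins per half-thick
filament, and a target opposing load of 120 pN. Two accounting
conventions are implemented and labelled in the output — one-sided (six
lengthening molecules: 72 pN at 35 nm, multiplier 120/72 ≈ 1.67) and
differential (both flanks, 144 pN) — because the published step from 12
pN/molecule to the "approximately 4×" stiffness conclusion is not
uniquely reconstructable; no acceptance quantity depends on it. The
absolute maximal active force per filament (P₀) is likewise not printed
and is left as a configurable constant.

## 7. Degenerate inputs, tolerances, tie-breaks

* Segmentation returns an **empty list with a warning** (not an error)
  when no ridge passes the filters; scoring an empty list errors with
  "no Z-disks to score".
* A segment whose coordinates are all identical is a degenerate fit and
  errors; ties in the TLS direction (perfect squares) resolve to
  whichever principal direction the SVD returns — the residuals are
  identical either way.
* Angular arithmetic is everywhere modulo 180° with differences wrapped
  to [−90°, 90°); the axial mean uses doubled-angle vector averaging.
* Gaussian-mixture EM (two components, 1-D) initializes at the 10th/90th
  distance percentiles, caps at 200 iterations, tol 1e-8 on the
  log-likelihood, and is reported only — never used to filter.
* Negative band areas after baseline subtraction clip to 0 with a
  warning; an ACTN2 integral at or below background drops that sarcomere
  with a warning.
* Particle detection contrast ("appropriate electron density") is a
  configurable minimum blob contrast, default 0.3 of the dynamic range,
  chosen on synthetic data — a convention, flagged as such.

## 8. Known limitations

* The fracture-area segmentation assumes Z-disks within ±30° of the
  dominant transverse direction; fibers imaged at extreme obliquity need
  the orientation gate widened.
* Particle diameters are estimated from the half-depth area of the raw
  image; below ~2 px diameter the size gate is resolution-limited.
* The viscoelastic generator is linear; real titin force–extension is
  markedly nonlinear across large SL ranges, so per-step SLS parameters
  are effective, local quantities.
* `thick_filament_lengths` pairs labels greedily by transverse order;
  densely overlapping filaments in heavily damaged sarcomeres can
  mis-pair, which mirrors the acknowledged snapshot nature of that
  measurement.
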