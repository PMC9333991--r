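---
title: "Models and methods behind mesomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mesomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mesomap)
```

mesomap analyses wide-field optical intrinsic signal imaging (OISI) of the
mouse dorsal cortex and validates every stage against a synthetic generator
with known ground truth. This vignette explains the models, the parameters
that matter, the numerical choices, and what the validation does and does
not establish.

## Spectroscopic model

Reflectance under sequential illumination at wavelengths
$\lambda \in \{478, 588, 610, 625\}$ nm follows the modified Beer–Lambert
relation

$$-\ln R_\lambda(t) = \left[\varepsilon_{HbO}(\lambda)\,\Delta HbO(t) +
\varepsilon_{HbR}(\lambda)\,\Delta HbR(t)\right] L(\lambda),$$

with $R_\lambda$ relative to its temporal mean (so baseline $R \equiv 1$
and only concentration *changes* are recovered). `invert_beer_lambert()`
divides $-\ln R$ by the per-wavelength pathlength and solves the resulting
$n_\lambda \times 2$ linear system per pixel and frame by QR least squares;
any two or more wavelengths are handled uniformly, and the condition number
of the extinction design is reported (8.6 for the four bundled LEDs).
$\Delta HbT = \Delta HbO + \Delta HbR$ is rebuilt and asserted after every
transform.

Extinction coefficients and pathlength factors are bundled as versioned
plain-text tables (`inst/extdata/`), linearly interpolated, and chosen for
the qualitative spectral structure the inversion needs — an isosbestic
point near 585 nm and strong deoxyhemoglobin dominance in the red. The
tables are configurable (`optics_model()`); analyses use only differential
quantities, so a global rescaling of $L$ rescales concentrations without
affecting correlations, thresholds expressed as fractions, or effect sizes.

## Synthetic cortex

The generator is the study's ground truth, a pure function of its seed.

* **Atlas** — a mirror-symmetric elliptical brain mask (default
  128 × 128 px at 0.078 mm/px, ≈0.8 cm² of cortex) with three midline
  landmarks for affine registration.
* **Resting networks** — nodes are Gaussian footprints
  ($\sigma = 0.03\,w$, centres ≥ ~11 px apart on a 64-px grid so a 3-px ROI
  disc sees < $10^{-4}$ of a neighbouring footprint; overlapping footprints
  would bias recovered correlations). Node time courses are white Gaussian
  series coloured by the symmetric square root of the target correlation
  matrix (PSD-checked at construction). The default `demo_network()` plants
  homotopic $r = 0.7$ and motor–visual $r = -0.4$, the anticorrelation
  coupling both hemispheres' motor nodes to both visual nodes, which keeps
  the target matrix PSD (pairing only within hemispheres does not).
* **Hemodynamic coupling** — $\Delta HbR = -0.4\,\Delta HbO$ (activation
  raises HbT); exposed as `hb_coupling`. Evoked amplitudes are specified in
  HbT, the analysed contrast.
* **Evoked responses** — a boxcar over each stimulation window convolved
  with a unit-peak gamma-variate impulse response
  ($h(t) = (t/t_p)^a e^{a(1-t/t_p)}$, peak 2 s, shape 2.5 giving ≈3 s
  FWHM), scaled to the requested peak amplitude. Lesions attenuate the
  response of any node whose centre falls in the lesion disc; a remapped
  site can switch on at a later session.
* **Noise** — independent white pixel noise plus an optional brain-wide
  shared fluctuation (`global_sd`), included so global signal regression
  has something real to remove.
* **Behavior / expression** — paw-contact times consistent with planted
  asymmetry means; Ct tables with log2 group effects on top of a stable
  reference gene.

What the generator does *not* emulate: vascular anatomy, photon transport,
motion, heartbeat/respiration, fluorescence contamination. Passing
parameter-recovery tests therefore shows the *analysis* is correct and
calibrated, not that real data meet its assumptions.

## Preprocessing

The pipeline order is spectroscopy → quality control → downsampling (RSFC
path) → band-pass → global signal regression → affine registration → shared
mask.

* **Quality control** flags runs whose global-trace variance exceeds 5× the
  median run or whose largest frame-to-frame jump exceeds 10× the median
  absolute frame difference; both multiples are configurable because no
  printed criteria exist.
* **Downsampling** (30 → 1 Hz) is non-overlapping block averaging —
  integration rather than decimation, so aliasing is suppressed and white
  noise variance drops by the rate ratio.
* **Band-pass** is a 5th-order Butterworth applied forward–backward
  (zero-phase), 0.009–0.08 Hz for resting analysis and 0.009–0.5 Hz for
  task sessions (task data stay at their native rate). Traces are demeaned
  before filtering; with a 0.009-Hz cut-off the step response of the filter
  otherwise rings across most of a 15-min run.
* **Global signal regression** projects each pixel on [1, global mean] and
  keeps the residual; residuals are orthogonal to the regressor, making the
  operation idempotent (a second pass sees a zero-variance global signal
  and returns the movie unchanged, with a warning).
* **Registration** solves the 6-parameter affine exactly from three
  landmark pairs; images are bilinearly resampled, masks
  nearest-neighbour-resampled and re-binarized.

## Evoked-response analysis

Blocks of `pre + stim + post` seconds (electrical default 5 + 10 + 35 s,
18 blocks) are baseline-corrected by the mean over [onset − 5, onset − 1) s
and averaged. Peak maps average 2 s before to 2 s after stimulus offset
(the symmetric window is a package choice; the source description of the
window is ambiguous). The response threshold is 75% of the maximum of the
group-averaged *baseline* peak map, reused for all mice and sessions;
comparisons are inclusive (ties respond). Magnitude is the maximum over
suprathreshold pixels and is explicitly missing when no pixel qualifies;
because any loss greater than 25% of the group maximum can empty the
suprathreshold set, `response_metrics()` accepts a `fallback_region`
(typically the baseline response footprint) in which sub-threshold
responses are still quantified — without it a > 70% loss would be
unmeasurable by construction. Area always counts suprathreshold pixels
(0 if none). T-maps are one-sample t statistics of per-block peak-window
responses (dof = blocks − 1, zero-variance pixels missing); Cohen's-D maps
compare mouse-level T values between groups with the n−1-weighted pooled
SD, restricted to pixels whose group-mean T exceeds 2 in either group.

## Resting-state connectivity and networks

ROI traces are unweighted pixel means; correlations are zero-lag Pearson,
Fisher-z transformed ($z = \operatorname{atanh} r$, $|r| \ge 1$ clipped to
$1 - 10^{-7}$). Matrix diagonals are excluded everywhere. Node degree
counts partners with $z \ge 0.4$ (inclusive; negative correlations never
count). Pixelwise matrices are computed on a configurable spatial subsample
(default every 2nd pixel) to bound memory.

**Spatial PCA** of a group correlation-difference matrix column-centres
the matrix, symmetrizes the result (exact when the planted structure is
built from mean-zero components), and eigendecomposes it. Components are
ordered by eigenvalue magnitude and `variance_explained` is
$|\lambda_i| / \sum_j |\lambda_j|$; the signed eigenvalue sum equals the
trace of the centred matrix (conservation check, $10^{-9}$). The
**permutation test** shuffles group labels (3000 iterations by default;
sampled with replacement, with a warning, when fewer distinct relabelings
exist), recomputes the difference-matrix eigenvalues, and flags observed
values above the null 90th percentile. With an empirical percentile of 200
draws the nominal type-I rate is ≈10.4%, which the calibration check
reproduces. Raw eigenvalue magnitudes are the test statistic; whether the
original analysis used raw eigenvalues or variance fractions is unstated,
and fractions can be obtained from the returned null matrix.

**ROI derivation** averages a PC map with its midline mirror, smooths with
a truncated renormalized Gaussian (default $\sigma = 2$ px; the original
kernel is unstated), keeps pixels at/above 85% of the positive maximum and
at/below 85% of the negative minimum, and labels 8-connected components
separately per hemisphere. **Recovery matrices** are group means of
$|z_{week4}| - |z_{week1}|$; group recovery differences test each edge's
group × time interaction as a Welch t between the groups' per-mouse
recovery values — the exact interaction contrast of the 2 × 2
repeated-measures design — with Benjamini–Hochberg control at q = 0.05.
Full repeated-measures ANOVA / mixed models are deliberately delegated to
standard routines and not re-derived.

## Photostimulation analysis

Block averaging (10-s stimulation, 50-s rest, 10-Hz movies) is the
denoiser; no band-pass is applied to block-averaged stimulus traces. The
seed is the mean over pixels within 4 px (≈310 µm) of the target; the
effective-connectivity map is raw Pearson r (not Fisher z, since the
downstream threshold at 0 is sign-based). The inhibition index counts mask
pixels with $r < 0$ strictly; a magnitude-weighted mode
($\sum |r|\,[r<0]$) is provided because the source wording is ambiguous
between a count and a sum, and the count (an area) is the default. The
photostim generator draws its noise once per seed, so sweeping the surround
weight at a fixed seed is a paired experiment — this is what makes strict
monotonicity of the index in the surround weight testable.

## Ancillary metrics

Paw-use asymmetry is $(\%L - \%R)/(\%L + \%R)$ computed from single-paw
contact times only (both-paw contact enters neither term; its handling is
unstated in the source and documented here as a package decision). Mice
with baseline |asymmetry| > 0.5 are excluded (strict). Infarct volume is
total section area × 0.3 mm. Comparative Ct uses
$2^{-\Delta\Delta Ct}$ against a reference gene and control-group mean;
fold changes are ratios of group means on the relative scale while t-tests
run on the log-scale $\Delta\Delta Ct$ values (variance-stabilizing).
Clustering normalizes genes to zero mean/unit variance across groups
(constant genes excluded), then average-linkage hclust on Euclidean
distance; leaf order is canonicalized by content-based dendrogram
reordering so that row permutations yield identical output.

## Problem sizes and tolerances

Validation runs at desk scale, chosen once: 64-px atlases for recovery
checks, a 45-min (n = 2700 at 1 Hz) session for correlation recovery —
matching the stated session acquisition of up to nine 5-min resting runs —
with tolerance $2/\sqrt{n-3}$ per edge; 2-Hz, 6-block task runs in the
study driver (the paradigm defaults remain 18/30 blocks); 200-run × 200-
iteration calibration of the permutation test. Round-trip and algebraic
identities are held to $10^{-9}$–$10^{-10}$ relative; statistical recovery
checks use 2-standard-error bands. At single-run length (n = 300) the exact
finite-sample SD of Fisher z slightly exceeds $1/\sqrt{n-3}$, which makes a
95%-coverage demand at the 2-SE tolerance marginal by construction; at
session length the discrepancy is negligible.

## Known limitations

No motion correction, hemodynamic deconvolution, ICA denoising, partial or
lagged connectivity, varimax/ICA decompositions, or graph metrics beyond
degree. The bundled optical tables are a compiled approximation adequate
for differential imaging, not a metrological reference. Reflectance noise
levels of the original acquisition are unreported; generator defaults are
explicit, configurable placeholders.
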