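---
title: "Methods: calibrated backscatter spectra, nuclei counting, and cohort statistics in qustr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated backscatter spectra, nuclei counting, and cohort statistics in qustr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`qustr` implements the analysis chain of a quantitative-ultrasound (QUS)
study of tumor response to chemotherapy: spectral biomarkers from raw RF
echoes, nuclei density from H&E histology, and the cohort statistics that
link the two. This vignette is the package's account of the science behind
each stage, of the parameters that matter, and of the design decisions taken
where the underlying procedure left choices open.

## 1. The spectral model

Backscattered RF from soft tissue is modeled as the transducer pulse
convolved with a random field of sub-resolution scatterers. The windowed
power spectrum of gated echo segments, averaged over independent scan lines
and divided by the spectrum of a perpendicular quartz-flat reflection at the
focus, estimates the tissue's backscatter transfer function with the system
response removed. Over the usable band this calibrated spectrum (in dB) is
summarized by an ordinary least-squares line:

* spectral slope **SS** (dB/MHz) — the regression slope, sensitive to
  effective scatterer size (larger scatterers steepen the roll-off);
* midband fit **MBF** (dB) — the fitted value at the band center,
  sensitive to scatterer concentration and acoustic impedance contrast.

Assumptions: diffuse (incoherent) scattering with many scatterers per
resolution cell; stationarity within the gate; no attenuation compensation
(the tumors sit a few millimetres under the skin at 6 MHz, where
attenuation shifts both groups almost equally).

### Averaging and conventions

* Line spectra are averaged in **linear power** before conversion to dB
  (the unbiased estimator; averaging in dB would bias every spectrum
  downward by ~2.5 dB for single-line chi-squared periodograms).
* Power dB means `10*log10(|FFT|^2)`, so doubling the RF amplitude adds
  exactly 6.02 dB to MBF and nothing to SS.
* Sample/line indices are 0-based with half-open gates; depth maps to
  samples by two-way travel at 1.54 mm/us (the soft-tissue convention).
* MBF is evaluated at the center of the measured band, not at the
  transducer's nominal frequency.
* Per-ROI (SS, MBF) values — not pooled spectra — are averaged over the
  three ROIs, giving each ROI equal weight in the tumor-level biomarker.

### The analysis band

The regression is confined to the contiguous interval around the reference
spectral peak where the reference stays within `threshold_db` of its peak.
The default is the **-6 dB band** (about 4.5–7.5 MHz for the default
pulse). This is deliberately narrower than bands sometimes used at lower
slope magnitudes: at the slopes this application encounters (-5 to -11
dB/MHz) the calibrated spectrum falls 30–70 dB across a wide band, so a
-15 dB band would place its upper edge ~40 dB below the in-band peak —
beneath any realistic noise floor — and bias the slope toward zero. The
threshold remains a parameter (`threshold_db`) for systems with flatter
targets.

## 2. The RF simulator and its normalization

Each scan line is generated as: Poisson-placed scatterers along depth
(default 60 per mm of line, ~15 per resolution cell), gamma-distributed
positive amplitudes (mean 1, CV 0.3), convolved with a Gaussian-envelope
pulse (6 MHz center, 50% fractional bandwidth at -6 dB, 35 MHz sampling),
shaped by a transfer function that is linear in dB over the generation band,
plus white Gaussian noise, then 16-bit quantization under a per-frame gain
recorded in metadata (so the huge quartz-flat echo and the faint tissue
echo both use the full integer range, as real acquisition chains do).

The simulator's contract is that the **analyzed** SS and MBF equal the
requested ground truth. Three details make that exact rather than
approximate:

1. **Windowed-periodogram deconvolution.** The analyzer's expected
   periodogram is the synthesis power spectrum convolved with the Hamming
   window's power kernel (incoherent smoothing), while the specular
   reference is smoothed coherently in amplitude. At steep slopes this
   asymmetry biases a naive construction by several tenths of a dB/MHz, so
   the synthesis filter is solved by a short fixed-point iteration such
   that the *expected calibrated spectrum* lies on the requested line
   (residual < 0.01 dB across the band).
2. **Noise accounting.** The white-noise level is set from the expected
   signal power (`noise_snr`, default 30 dB), and its flat expected
   periodogram is subtracted from the deconvolution target. Slopes steeper
   than about -12 dB/MHz push the upper band edge below the noise floor,
   where no normalization can avoid bias; the recovery contract is
   therefore stated for slopes in [-12, 0] at the default SNR. At the
   study's group means the Monte-Carlo bias is < 0.1 dB/MHz (SS) and
   < 0.3 dB (MBF).
3. **Gate and density anchoring.** Calibrated diffuse-vs-specular spectra
   scale with gate length and scatterer density (plane-reflector
   calibration physics), so MBF ground truth is anchored at the default
   gate (192 samples = 4.22 mm) and reference density (60/mm). Doubling
   the density raises the analyzed MBF by 10*log10(2) = 3.01 dB, the
   incoherent-scattering law, and amplitude scaling by `a` shifts it by
   `20*log10(a)` exactly.

The generator does **not** model diffraction, beamforming, elevational
focusing, frequency-dependent attenuation, or spatially correlated scatterer
populations; per-line scatterer trains are independent, so speckle has no
lateral correlation. Passing validation therefore establishes the
correctness of the analysis chain under the stated generative model, not the
realism of any particular tissue.

## 3. The H&E field generator and nuclei counting

Counting reproduces the vendor-software procedure: HSI thresholding (the
standard arccos hue formulation scaled to 0–255; intensity <= 120 selects
dark hematoxylin-stained pixels), 8-connected components, area >= 50 px and
bounding-box width/height ratio in [0.5, 2], then watershed splitting on the
Euclidean distance transform (the "split objects" equivalent; `tolerance`
and `ext` control the minimum seed separation). Counts of ten fields are
averaged into the per-tumor density.

The synthesizer draws nuclei as dark blue-purple ellipses (radius 7.5 ± 0.8
um at 0.8 um/px — a ~15 um nuclear diameter; eccentricity and orientation
jittered within the aspect gate) on a pink eosin-textured background, with a
configurable fraction placed as touching pairs. Placement keeps nuclei
disjoint whenever the requested density allows and relaxes toward dense
packing otherwise, so sparse fields are counted **exactly** and control-like
densities (334/HPF in a 512 px field, ~35% coverage) are recovered within a
few percent. Not emulated: stain variability, out-of-focus blur, stromal
structures, apoptotic fragments, and true whole-slide hotspot selection
(fields are generated directly at the requested density).

## 4. Statistics

* **t-test**: pooled-variance Student's (Welch available), two-sided.
* **Normality/variance checks**: one-sample Kolmogorov-Smirnov against a
  normal with estimated parameters (conservative p-values, as in common
  statistics packages) and Levene's test centered at the mean.
* **Classifier**: the original software's default discriminant — a
  two-class linear discriminant with pooled covariance and equal priors —
  applied leave-one-out; treated is the positive class and ties break
  toward control. The implementation is closed-form and is verified
  prediction-for-prediction against `MASS::lda(CV = TRUE)` in the tests.
  The two biomarkers are used jointly (the natural reading of a
  two-feature discriminant); single-feature LOOCV is available by passing
  one column.
* **Volume**: prolate ellipsoid, pi/6 * length * width * depth.
* **Echogenicity**: envelope (analytic signal) -> log compression ->
  8-bit mapping on a fixed display reference (the calibration echo peak)
  with a display gain, so intensities are comparable across frames.

### What replication shows about the published classification rates

Replicating the 12-vs-12 design from the published group means/SDs (features
independent within group, the default since the within-group correlation is
unreported) gives ensemble means of ~84% accuracy, ~86% sensitivity and
~81% specificity over 1000 cohorts. A single published cohort is one draw
from this ensemble: per-cohort specificity has an SD of ~0.11, so an
observed 11/12 (91.7%) lies within about one SD of the ensemble mean. The
asymmetry direction (sensitivity > specificity in the ensemble) follows
from the control group's larger SDs on both features — the pooled-covariance
boundary misclassifies the wider class more often.

## 5. Numerical choices and degenerate inputs

* Gates shorter than 64 samples are rejected (too few bins); fewer than 3
  in-band bins rejects the regression; a single-bin band is rejected.
* Zero-power spectral bins are floored at -300 dB (all-zero segments warn).
* A constant sample makes the KS test undefined (reported `NA`); zero
  pooled variance with equal means returns t = 0, p = 1, with unequal
  means it is an error.
* A singular pooled covariance in the discriminant falls back to its
  diagonal with a warning.
* Fewer than one expected scatterer per resolution cell warns (coherent
  regime: the spectral ground-truth contract is void).
* All generators are pure functions of their arguments including the seed;
  derived per-sample seeds keep streamed and batch cohort generation
  identical, and pipeline artifacts are byte-identical for identical
  config + seed.

## 6. Problem sizes

The shipped tests validate parameter recovery with 100 seeds per group
parameterization (frames of 64 lines x 2045 samples), histology recovery
with 10 fields per group at 512 px, classifier replication with 1000
cohorts, and t-test calibration with 5000 null cohorts; the full pipeline
examples run 3 + 3 tumors with two 160 px fields each. These sizes give
Monte-Carlo standard errors well below the stated tolerances (e.g. SE
~0.02 dB/MHz for the slope means, ~0.004 for replicated LOOCV accuracy).

## 7. Limitations

The simulator validates the chain, not tissue realism (Section 2); the
histology generator cannot test hotspot-selection behavior; attenuation and
scatterer-size inversion are out of scope (SS and MBF are reported as-is);
and echogenicity in display units depends on the chosen display mapping, so
only its treated-vs-control ordering — not its absolute value — is
meaningful.
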