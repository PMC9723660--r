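---
title: "Microscale pH mapping with ratiometric whole-cell biosensors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microscale pH mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micropHmap)
```

## The measurement model

micropHmap analyses time-lapse fluorescence recordings of immobilized
bacterial biosensor cells expressing a periplasmic, ratiometric pH-sensitive
GFP (a pHluorin2-class sensor). The sensor is excited alternately at 475 nm
and 395 nm and imaged at 510 nm emission; acidification increases the
475-excited emission and decreases the 395-excited one, so the per-cell
excitation ratio

$$R = \frac{I_{510\text{-}475}}{I_{510\text{-}395}}$$

(both intensities background-corrected) rises as environmental pH falls.
Because the readout is a ratio, it cancels expression level, illumination
inhomogeneity and bleaching to first order — the properties that make the
approach usable over a 48 h time-lapse.

Within the sensor's linear response range the calibration is a straight
line,

$$R(\mathrm{pH}) = \alpha\,\mathrm{pH} + \beta, \qquad \alpha < 0,$$

inverted per cell as $\widehat{\mathrm{pH}} = (R - \beta)/\alpha$, with
ratio precision propagating as
$\sigma_{\mathrm{pH}} = \sigma_R / |\alpha|$. The package's default
photophysics carries the two-point unbuffered standard line through
(pH 7.4, R = 0.45) and (pH 5.0, R = 1.59), i.e. $\alpha = -0.475$,
$\beta = 3.965$.

A note on published precision figures: reported ratio-to-pH precision pairs
(±0.01 ratio ≈ ±0.05 pH near neutral; ±0.10 ≈ ±0.15 pH in the acid range)
imply *local* slopes of about −0.2 and −0.67 — both inconsistent with the
single global slope −0.475. A strictly linear sensor cannot reproduce both
pairs; the full calibration table behind them is not available. The package
retains the linear model (the calibration's own description, with
R² ≈ 0.99) and propagates precision through the global slope; users with a
measured piecewise calibration can fit per-range curves instead.

## Pipeline stages

1. **Simulation** (`generateField`, `placeCells`, `renderFrame`) — builds a
   known-truth scene and renders it to two-channel 16-bit images.
2. **Quantification** (`segmentCells`, `measureCells`, `linkTracks`) —
   detects cells, extracts background-corrected channel means, forms
   per-cell ratios with QC flags, links frames into tracks.
3. **Calibration** (`fitCalibration`, `applyCalibration`) — fits the
   ratio-vs-pH line on per-level means and converts ratios to pH,
   flagging values outside the calibrated range.
4. **Mapping** (`looCv`, `crossValidateResolutions`, `buildMap`) —
   selects the finest trustworthy grid resolution by leave-one-out
   cross-validation, then interpolates per-cell pH by inverse distance
   weighting.
5. **Temporal analysis** (`frameStats`, `gradientMetric`,
   `gradientStability`, `onsetTime`, `influenceZoneWidth`,
   `diffusionTime`) — trajectories, microscale gradients and their
   stability, onset of acidification, and the zone-of-influence and
   diffusion-time arithmetic.

`runPipeline` orchestrates all stages with a single seeded configuration
and writes a manifest (config hash, seed, per-file checksums), so a run is
reproducible byte for byte.

## The synthetic scene generator

The generator emulates the study conditions: a 0.4 × 0.8 mm observation
area carrying ~2200 cells/mm² of immobilized ~2 µm biosensor cells
(≈704 cells in expectation, matching the >700 tracked in the emulated
experiment), imaged hourly for 48 h.

**Cell placement** is homogeneous Poisson: count ~ Poisson(density × area),
positions uniform. **Rendering** draws each cell as a disk whose two
channel amplitudes split a pH-independent total signal $A$:

$$I_{475} = A\frac{R}{1+R}, \qquad I_{395} = \frac{A}{1+R},$$

so the per-cell ratio is exactly $R$ and total brightness does not depend
on pH — segmentation on the channel sum therefore cannot be pH-biased.
The raster is blurred by a Gaussian point spread (σ = 0.5 µm), backgrounds
are added, and Poisson shot noise plus Gaussian read noise are applied —
the standard camera model. Bleaching is geometric decay on $A$ only; the
ratio is invariant to it by construction, and that invariance is what the
tests assert. Defaults ($A$ = 1000 counts, backgrounds 100, read noise 3)
give a per-pixel SNR of roughly 20–30 at neutral pH; absolute counts are
free parameters of the emulation, since no camera gain is specified for
the emulated instrument.

**Field kinds** cover the qualitative regimes of the emulated experiment:

- `uniform` — fungus-free control (pH 6.9 agarose);
- `ramp` — whole-field acidification from 6.9 to ~5.0 over 48 h;
- `gradient_patch` — static acidic depressions (amplitude 1.4 pH units)
  with sigmoidal edges. The `length_scale_um` parameter is defined as the
  *separation over which the full plateau-to-plateau contrast is
  observed*: the sigmoid transition is concentrated in the central half of
  that distance (steepness 16/L). The looser reading — spreading the whole
  transition across the quoted distance — makes the planted contrast
  unobservable at realistic cell spacing: points 20 µm apart would never
  straddle both plateaus. Since the emulated observation is plateau values
  *at* ≈20 µm separation on a 3 µm map, the transition itself must be
  narrower than the quoted distance;
- `grf` — a stationary Gaussian random field (smoothing-kernel sd =
  correlation length, empirically standardized to the requested mean/sd),
  used for interpolation-accuracy studies. The validation scenes use
  sd 0.4 and mean 5.3: a late-colonisation snapshot whose ±2 sd span
  (≈1.6 units) matches the reported microscale range pH 4.4–5.8;
- `hyphal_front` — an acidification front travelling from the x = 0 edge
  at the hyphal extension rate, leading the (virtual) tips by a
  configurable lead time, for onset-detection tests.

What the generator does **not** emulate: real optics (objective/NA physics,
focus drift), hyphal autofluorescence and shading, three-dimensional
growth, motile or dividing reporter cells, and spatially correlated
backgrounds. Passing recovery tests therefore demonstrate the
*analysis chain* is unbiased and precise under the stated noise model —
not that any real microscope dataset would meet the same numbers.

## Numerical and design choices

**Segmentation.** The channel-sum image is smoothed (Gaussian, sd 1 px)
and thresholded globally by Otsu's method. Because foreground occupies
only ~1% of these frames, a single Otsu pass settles near the background
mode and fattens cells until neighbours ~3 µm apart merge; the default
therefore applies a second Otsu pass restricted to above-threshold pixels
(recursive Otsu, the usual unbalanced-class correction). This is still a
single global threshold — shape-based splitting of genuinely touching
cells (watershed) is out of scope, and cells closer than ~2.6 µm remain
one component. At 2200 cells/mm² that affects ~5% of cells (half of each
merged pair is lost), which is the dominant term in the ~97% single-frame
recovery the test-suite verifies. Components outside 1–20 µm² are
discarded; 8-connectivity is used throughout.

**Background.** Median of non-ROI pixels per channel per frame: robust to
the ~1% cell coverage and reproducible, unlike a hand-drawn background
region. Corrected intensities are ROI means minus background; ratios of
means equal ratios of integrated densities over a shared ROI, and means
are area-independent.

**QC policy.** Cells with non-positive corrected intensity
(`negative_after_correction`), weak denominator signal (`low_signal`,
i395 < 3 × read noise) or calibrated pH outside the curve's range plus a
0.2-unit grace margin (`out_of_calibration_range`) are excluded from
mapping rather than imputed or clamped — extrapolating a sensor past its
calibrated range is not defensible. The synthetic calibration spans
pH 4.0–8.2 (the span of the emulated calibration experiment), keeping the
validity floor clear of the lowest pH the maps report; a calibration that
stops exactly at that pH would censor the acid noise tail and bias
gradient amplitudes low.

**Tracking.** Greedy nearest-neighbour linking (radius 2 µm, up to 2
missed frames), adequate for physically immobilized cells; it is not a
global assignment and is a documented limitation for motile ones.

**IDW.** $\hat z = \sum_i z_i d_i^{-p} / \sum_i d_i^{-p}$ with $p = 2$
(the near-universal default; the exponent is configurable) over the
$k = 25$ nearest observations. The all-points neighbourhood is available
(`IDWParams(k = Inf)`) but is *not* the default: in two dimensions the
$d^{-2}$ weight tail diverges logarithmically, so with ~700 observations
every prediction receives a substantial contribution from the far field
and shrinks toward the global mean. On study-geometry test fields this
visibly inflates map error (bull's-eyes at cells, flattened structure
between them) and fails the package's own field-recovery requirement;
k = 25 corresponds to a ~60 µm neighbourhood radius at the study density,
local enough to preserve 20 µm structure while averaging noise. Targets
within 10⁻⁹ µm of an observation return the exact (mean) observed value.

**Resolution-dependent cross-validation.** Plain leave-one-out at the
observation's own position would be independent of grid resolution. The
package instead predicts each held-out cell at the centre of the r-grid
cell containing it, so coarser grids genuinely displace the prediction
point and score worse — one consistent reading of per-resolution CV, and
the construction under which the selection rule (smallest r with
CV R² ≥ 0.79 and mean absolute percentage error < 4.5%) reproduces the
reported choice of 3 × 3 µm. Prediction error is MAPE on pH units;
R² is reported as NA when the held-out values have zero variance.

**Gradient metrics.** `gradientMetric` scans all node-pair offsets within
the window (exact, ties broken in row-major order);
`gradientStability` ranks nodes by their maximum 8-neighbour
|ΔpH|/distance and reports the Jaccard overlap of top-decile sets between
consecutive frames. Independent random maps give an expected Jaccard of
$f^2/(2f - f^2) \approx 0.053$ at $f = 0.1$; a planted static gradient is
called temporally stable when consecutive-frame overlap stays ≥ 0.5 —
an order of magnitude above the chance level.

**Onset detection** is a k·σ exceedance rule against the control series
(first frame with mean pH below the control baseline minus k times the sd
of control frame means, k = 3 by default): a deliberately simple,
automation-friendly stand-in for per-frame hypothesis testing, which is
out of scope.

**Diffusion time** uses $t = x^2/(gD)$ with geometry factor $g = 2$ (the
1-D mean-squared-displacement convention) and the proton diffusivity
$D = 9.3\times10^{-5}\ \mathrm{cm^2\,s^{-1}}$; for 20 µm this gives
0.0215 s. Published figures of ~0.08 s for the same distance are not
reproducible from any standard geometry factor (1, 2, 4 or 6 with x = 20
µm); both $x$ and $g$ are therefore exposed as arguments rather than
hard-coded, and the discrepancy is documented rather than resolved.

## Problem sizes used by the tests

The validation suite runs the full study geometry where the claim demands
it — recovery fractions and gradient amplitudes are checked on
0.4 × 0.8 mm scenes with ~700 cells (49 frames for the trajectory
endpoint, 1–3 frames elsewhere) — and small cutout scenes (≤ 0.3 × 0.15
mm) for arithmetic-level properties where scene size is irrelevant.
Property tests at toy sizes deliberately avoid map-accuracy assertions:
with only a few dozen observations the k = 25 neighbourhood spans most of
the field and IDW legitimately flattens structure, which is a scale
effect, not an implementation defect.

## Known limitations

- Touching cells (< ~2.6 µm apart) are segmented as one; at much higher
  densities than ~2200 cells/mm² recovery degrades accordingly.
- The linear calibration cannot represent the sensor's sigmoidal response
  outside its linear range; out-of-range cells are dropped, not modelled.
- IDW is an exact, deterministic interpolator with no uncertainty model;
  kriging-style variance maps are out of scope.
- Greedy tracking assumes immobilized cells.
- The acidification onset rule presumes a stationary control series.
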