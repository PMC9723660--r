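# micropHmap

Micrometre-scale pH mapping from time-lapse images of immobilized
ratiometric whole-cell biosensors.

Bacterial reporter cells carrying a periplasmic, dual-excitation
pH-sensitive GFP (pHluorin2 class) act as thousands of independent ~2 µm
pH probes scattered across a surface. Imaged at 510 nm emission under
alternating 475 nm / 395 nm excitation, each cell yields a
background-corrected intensity ratio

    R = I(510–475) / I(510–395)

that increases as environmental pH falls and, within the sensor's linear
range, obeys a straight standard curve `R = α·pH + β` (α < 0). From
two-channel 16-bit image stacks micropHmap produces calibrated per-cell pH
tracks, interpolates them onto regular micrometre grids by inverse distance
weighting (IDW) with leave-one-out cross-validated selection of the finest
trustworthy grid resolution, and quantifies the resulting microenvironment:
whole-field acidification trajectories, microscale pH gradients and their
temporal stability, acidification onset ahead of a colonisation front, and
zone-of-influence / diffusion-time estimates.

The package is written for microbiologists and microscale biogeochemists
who run (or plan) whole-cell-biosensor experiments — e.g. mapping how
fungal hyphae acidify their surroundings (the mycosphere) — and for
methods developers who need a fully synthetic, ground-truth-controlled
test bed for such pipelines. A built-in scene generator renders noisy
two-channel stacks from known pH fields (uniform controls, acidification
ramps, static gradient patches, Gaussian random fields, travelling
acidification fronts), so every stage can be validated against known truth
without any external data.

## Worked example

Simulate one frame of the default 0.4 × 0.8 mm scene (~700 cells at
2200 cells/mm²) over a spatially correlated pH field, quantify it,
calibrate, cross-validate map resolutions, and interpolate:

```r
library(micropHmap)

cfg    <- SceneConfig(nFrames = 1L, seed = 11L)
phys   <- Photophysics()
field  <- generateField(cfg, "grf",
                        list(correlation_length_um = 50, sd = 0.4, mean = 5.3))
layout <- placeCells(cfg)
pair   <- renderFrame(field, layout, phys, cfg)

obs   <- measureCells(segmentCells(pair), pair, readNoiseSd = 3)
curve <- fitCalibration(simulateCalibration(phys, seed = 12L))
curve
#> CalibrationCurve (unbuffered): R = -0.4788 pH + 3.993, R^2 = 1, pH 4-8.2
obs <- applyCalibration(obs, curve)

report <- crossValidateResolutions(obs, resolutions = c(1, 2, 3, 4, 5))
report
#> CVReport (leave-one-out):
#>  resolution_um cv_r_squared prediction_error_pct   n
#>              1    0.8999381             1.932547 671
#>              2    0.8996651             1.934678 671
#>              3    0.8995770             1.937978 671
#>              4    0.8992513             1.931393 671
#>              5    0.8982743             1.951042 671
#>   selected: 1 um (R^2 >= 0.79, error < 4.5%)

map <- buildMap(obs, selectedResolution(report), frame = 0L)
map
#> InterpolatedMap frame 0: 399 x 792 nodes @ 1 um from (6.94231, 0.694444), n = 671
#>   pH range [4.257, 6.399]

gradientMetric(map, 20)$max_delta_ph
#> [1] 0.7657064
influenceZoneWidth(18, 100)
#> [1] 1800
diffusionTime(20)
#> [1] 0.02150538
```

Reading the output: 671 of the ~700 planted cells were segmented,
measured and calibrated (curve slope −0.479, essentially the planted
−0.475). Leave-one-out CV predicts each cell from all others at the
centre of its grid cell; every candidate resolution clears the accuracy
thresholds (CV R² ≥ 0.79, error < 4.5%) because imaging noise here
contributes only ~0.06 pH units per cell, so the selector takes the finest
grid. With per-cell noise at the sensor's acid-range worst case (0.15 pH
units) CV R² at 3 µm drops to ~0.8 — the accuracy regime in which the
emulated study operated at its chosen 3 × 3 µm resolution (the package's
acceptance tests pin exactly that scenario down). The map stays within the observed pH range by
construction (IDW is a convex combination); the maximal contrast within
any 20 µm window of this smooth random field is 0.77 pH units. The last
two numbers are the analytic microscale summaries: an 18 h acidification
lead at a 100 µm/h hyphal extension rate implies a 1800 µm zone of
influence, and a proton crosses a 20 µm gradient by free diffusion in
~0.02 s — which is what makes hour-stable 20 µm pH gradients remarkable.

A full seeded run of every stage (simulate → quantify → calibrate → map →
analyze, with a checksummed manifest) is one call; the default
configuration simulates a late-colonisation snapshot (a static acidic
patch with a 1.4-unit, 20 µm edge) at the study geometry:

```r
res <- runPipeline(list(seed = 1L, scene = list(n_frames = 3L),
                        map_frames = 2L), outDir = "run1")
res$gradients
#>   frame max_delta_ph window_um jaccard_vs_prev
#> 1     2     1.498217        20              NA
```

The planted 1.4-unit contrast comes back as 1.50 after the full
image-to-map round trip (~40 s for three frames on one CPU).

or, from a shell, via the bundled thin CLI
(`inst/scripts/phmap.R`): `Rscript phmap.R all --config scene.yaml
--out run1 --seed 1`.

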