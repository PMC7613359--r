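# vigsa

Global sensitivity analysis of vegetation indices over coupled leaf–canopy
radiative transfer simulations.

## What it is for

Vegetation indices (VIs) — NDVI, GNDVI, water and leaf-area indices —
are used throughout optical remote sensing as fast proxies for leaf
chlorophyll content (LCC), leaf water content (LWC) and leaf area index
(LAI). Every index, however, also responds to *confounding* variation:
other leaf constituents, canopy structure, soil background, illumination.
`vigsa` quantifies that robustness for scientists designing or selecting
indices: it simulates top-of-canopy reflectance across the full plausible
range of leaf and canopy variables with radiative transfer models (a
four-parameter plate leaf model coupled to a four-stream turbid-medium
canopy for homogeneous vegetation, and to a hybrid geometric-optical
forest model), computes VIs on the simulated scenes — optionally after
convolution to the band settings of Landsat 8, MODIS, Sentinel-2,
Sentinel-3 or EnMAP — and attributes each index's variance to the model
inputs with variance-based (Sobol') sensitivity indices.

## Method in brief

For a model output $y=f(x_1,\dots,x_k)$ with independent inputs on the
unit hypercube, the package estimates the first-order and total-effect
Sobol' indices

$$S_i = \frac{\mathbb{V}[\mathbb{E}(y\mid x_i)]}{\mathbb{V}(y)},\qquad
S_{Ti} = \frac{\mathbb{E}[\mathbb{V}(y\mid x_{\sim i})]}{\mathbb{V}(y)},$$

with the radial Saltelli scheme: base matrices $P$ and $Q$ (halves of an
$N\times 2k$ Sobol' low-discrepancy sample) plus $k$ matrices $P_Q^{(i)}$
that differ from $P$ in column $i$ only — exactly $N(k+2)$ model runs,
with every VI computed from the same simulated spectra. A registry ships
the published LCC/LWC/LAI index sets with per-sensor applicability, and
arbitrary user formulas over band roles and `rho(wavelength)` terms are
accepted. The bundled leaf-coefficient calibration and soil spectrum are
**synthetic** (built in code, emulating the published calibrations, which
are not redistributable here); real calibrations can be supplied as
plain-text tables.

## Worked example

Which variables drive NDVI, GNDVI and a green/NIR simple ratio under a
homogeneous canopy, as seen by MODIS?

```r
library(vigsa)
cfg <- runConfig(model = "PROSAIL", N = 500, sensor = "MODIS",
                 vi = c("NDVI", "GNDVI", "SR:550/800"))
run <- runViGsa(cfg)
print(run)
#> Vegetation-index GSA run: PROSAIL / MODIS, N = 500, k = 8 (5000 model runs)
#> Total-effect indices (STi):
#>                N   Cab Cw    Cm   LAD   SZA soil_coeff   LAI
#> NDVI       0.007 0.590  0 0.014 0.121 0.039      0.025 0.371
#> GNDVI      0.015 0.762  0 0.024 0.059 0.023      0.009 0.226
#> SR:550/800 0.009 0.759  0 0.017 0.067 0.019      0.011 0.235

round(normalizeTotalEffects(run$results$NDVI), 3)
#>          N        Cab         Cw         Cm        LAD        SZA soil_coeff        LAI
#>      0.006      0.505      0.000      0.012      0.104      0.033      0.022      0.318
```

Reading: chlorophyll content carries a total effect of 0.59–0.76 for all
three indices — they are chlorophyll-driven above all — while leaf area
(total effect 0.23–0.37) is the main confounder; NDVI's variability is
~51% chlorophyll and ~32% leaf area in share terms, so as an "LAI index"
it is far from specific. Water, dry matter and soil brightness are nearly
irrelevant at these band settings.

Other entry points: `runSpectralGsa()` (per-wavelength total effects on
the native 1-nm or 5-nm grid), `convergenceScan()` (stability of the
estimates versus sample size), `builtinRegistry()` / `listIndices()` /
`listSensors()`, and the plumbing functions (`generateUnitDesign()`,
`prospect4()`, `sailTOC()`, `informTOC()`, `convolveToSensor()`,
`evaluateVi()`). A thin command-line wrapper with YAML/JSON configs lives
at `inst/scripts/vigsa` (`vigsa run --config cfg.yaml`, `vigsa spectral`,
`vigsa convergence`, `vigsa list-indices`, `vigsa list-sensors`).

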