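# ramanmcr

Chemical mapping of softwood tissue from confocal Raman hyperspectral
images: multiset MCR-ALS unmixing with the full preprocessing and
identification chain around it.

Confocal Raman microscopy records a complete Raman spectrum at every pixel
of a tissue section. In conifer wood those spectra mix the structural
cell-wall polymers (lignin; cellulose in two crystal orientations relative
to the laser polarization) with heartwood extractives — lignans,
flavonoids, oleoresin — whose sub-cellular distribution is of interest for
understanding natural decay resistance. `ramanmcr` turns a group of such
images into component spectra, per-pixel distribution maps and substance
assignments. It is aimed at plant cell-wall spectroscopists and
chemometricians who want a scripted, reproducible version of this
analysis, and it ships a synthetic-scene generator with exact ground truth
so every stage can be validated.

## The method

The data model is bilinear: with the pixel spectra of one or several
images stacked into a matrix *D* (rows = pixels, columns = wavenumber
channels),

> D = C Sᵀ + E

where *C* ≥ 0 holds per-pixel component abundances (the distribution
maps), the rows of *Sᵀ* are component spectra, and *E* is the residual.
The package implements:

* **Preprocessing** — cosmic-ray removal (third-order running median per
  channel), cluster-adaptive asymmetric least squares baseline correction
  (k-means on area-normalized spectra; per-cluster smoothness λ and
  asymmetry p), PCA denoising, Savitzky–Golay first derivatives
  (order 2, window 11), spectral trimming, 2-norm normalization.
* **Multisets** — column-wise augmentation of image groups over a shared
  wavenumber axis, optional per-image-norm scaling, and a binary
  images × components *correspondence* matrix declaring components absent
  from particular images.
* **Decomposition** — component-count estimation from the singular value
  trace (with expert override), SIMPLISMA purest-pixel initial estimates
  (10% noise margin) on zero-order data, derivatized, then MCR-ALS in
  first-derivative space: non-negativity on *C* only (active-set
  non-negative least squares, not clipping), unit-norm spectra, hard
  correspondence zeros, LOF/R² fit statistics
  (LOF = 100·√(ΣE²/ΣD²), R² = 100 − LOF²/100).
* **Recovery & identification** — zero-order component spectra via the
  pseudoinverse of the concentration profiles,
  Sᵀ = (CᵀC)⁻¹CᵀD₀; joint PCA of components and reference spectra with
  venetian-blinds cross-validation; substance assignment by marker-band
  matching against a built-in band table per excitation wavelength
  (532/785 nm).
* **Synthetic scenes** — tracheid-like layouts (S2 wall, cell-boundary
  ring, lumen, ray, droplets), marker-band-derived component spectra,
  region-dependent fluorescence baselines, Gaussian noise, cosmic-ray
  spikes and per-image absence flags, all reproducible from a seed.

## A worked example

Simulate a two-image 785 nm group in which the flavonoid component is
absent from the second image, run the full pipeline with three components,
and inspect the result:

```r
library(ramanmcr)

cfg <- default_config("larch-like")
cfg$simulate$absent <- list(c(2L, 3L))   # component 3 absent from image 2
cfg$simulate$width <- 24L; cfg$simulate$height <- 24L

state <- run_pipeline(cfg, "run1", seed = 7, n_components = 3)
pipeline_report("run1")
#> model: k = 3, LOF = 1.285 %, R2 = 99.9835 %, 3 iterations (converged)
#> rank estimate: chosen_k = 13 (override 3)
#> C1  -> Cellulose perpendicular      (score 1.00)
#> C2  -> Lignin                       (score 1.00)
#> C3  -> Flavonoids                   (score 0.95)

glance(state$model)
#> # A tibble: 1 × 5
#>       k lof_percent r2_percent n_iter converged
#>   <int>       <dbl>      <dbl>  <dbl> <lgl>
#> 1     3        1.29      100.0      3 TRUE
```

The model explains 99.98% of the variation of the derivative multiset with
a lack of fit of 1.3%, and each resolved component is top-ranked as the
substance that generated it. Because the run is simulated, the recovered
spectra and maps can be scored against the ground truth:

```r
match_components(state$recovered, state$truth$spectra,
                 C_est = state$model$C, C_true = state$truth$true_C)
#>   cosine map_r
#> 1  0.976 0.994
#> 2  0.998 0.954
#> 3  0.959 0.994
```

Spectral cosines of 0.96–1.00 and map correlations of 0.95–0.99 mean the
decomposition recovered both the chemistry and the spatial distributions
through baselines, noise and spikes; the constraint forced the absent
component's concentrations in image 2 to exactly zero. The scree-based
component estimate (13) illustrates why the count is an expert decision:
residual background directions inflate the trace, and `n_components`
overrides it, mirroring how the analysis is done in practice.

The run directory holds the cubes (`image01.csv`, …), recovered spectra,
per-image maps (CSV + PNG), identification report (JSON + text) and a
provenance log of every parameter applied.

Plotting: `autoplot(state$model)` draws the resolved spectra,
`plot_maps(state$model$C[1:576, ], 24, 24)` the first image's maps, and
`autoplot()` on a `pca_result` the component/reference score plot.

A command-line wrapper with the same stages
(`simulate`, `preprocess`, `decompose`, `recover`, `identify`, `run-all`,
`report`) is installed at
`system.file("cli", "ramanmcr", package = "ramanmcr")`.

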