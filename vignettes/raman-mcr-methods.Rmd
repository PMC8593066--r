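---
title: "Resolving wood extractives from confocal Raman images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving wood extractives from confocal Raman images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(ramanmcr)
```

## The problem

Confocal Raman microscopy maps the chemistry of plant tissue at
sub-micrometre resolution: each pixel of an image carries a full Raman
spectrum, so an image is a cube of pixels x wavenumber channels. In conifer
wood, such images mix the signatures of structural cell-wall polymers
(lignin, cellulose in two crystal orientations relative to the laser
polarization) with heartwood extractives — lignans, flavonoids and oleoresin
constituents deposited when sapwood turns into heartwood and thought to
underlie natural decay resistance. The analysis task is unmixing: decompose
the observed cube into a small number of component spectra and per-pixel
abundance maps, then say which substance each component is.

`ramanmcr` implements that full chain and, because real instrument data of
this kind are rarely deposited, ships a synthetic-scene generator with exact
ground truth so every stage can be validated end to end.

## The model

The data model is bilinear. With pixels of one or several images stacked
into a matrix $D$ (rows = pixels, columns = channels),

$$D = C\,S^\top + E,$$

where $C \ge 0$ holds the per-pixel component abundances (the distribution
maps, refolded to images for display), the rows of $S^\top$ are the
component spectra, and $E$ is residual noise. The model is fitted by
multivariate curve resolution — alternating least squares (MCR-ALS):
starting from initial spectra, alternate exact constrained least-squares
updates of $C$ and $S^\top$ until the lack of fit,
$\mathrm{LOF} = 100\sqrt{\sum E^2 / \sum D^2}$, stops improving. The
explained variation is $R^2 = 100\,(1 - \sum E^2/\sum D^2)$, so
$R^2 = 100 - \mathrm{LOF}^2/100$ identically — a useful internal consistency
check that the tests assert to $10^{-8}$.

Decomposition runs in **first-derivative space**: fluorescence backgrounds
survive baseline correction only imperfectly, and a Savitzky-Golay first
derivative suppresses what remains while preserving band structure. The
constraints are chosen accordingly:

* non-negativity on $C$ only — derivative spectra are signed, abundances are
  not. Enforced by per-pixel active-set non-negative least squares (a
  Lawson-Hanson solve on the normal equations), never by clipping, because
  clipping does not minimise the ALS objective. Tests compare every update
  against `pracma::lsqnonneg` row by row to $10^{-8}$.
* rows of $S^\top$ normalized to unit Euclidean norm each iteration, with a
  compensating column scaling of $C$ so the product $CS^\top$ — and hence
  the LOF trace — is unchanged. With exact half-steps the trace is then
  monotone non-increasing, which the tests check.
* an optional **correspondence-among-images** constraint: a binary images x
  components matrix declaring components absent from particular images of a
  multiset. Absent blocks of $C$ are excluded from the fit (not zeroed after
  the fact), which is the exact constrained minimiser and leaves exact
  zeros.

### Multisets

Images are grouped (by species and anatomical feature: tracheids, rays,
resin channels) and column-wise augmented: pixel rows of all images stacked
over a shared wavenumber axis, so the group is resolved jointly with one set
of component spectra. Optionally each image block is divided by its
Frobenius norm first; this balances images of different overall intensity
and is worthwhile for some groups and not others, so it is a flag
(`normalize_by_image_norm`). Block bookkeeping uses 1-based closed row
ranges, the natural R convention.

### Initial estimates and rank

The number of components is first estimated from the singular values of the
multiset: the chosen $k$ is the smallest one after which the relative drop
between consecutive singular values stays below a threshold (default 0.05)
for a stability window of 3 — the "flattening" of the scree. Machine-zero
singular values are treated as flat. The full trace is always returned
because in practice the final choice weighs fit statistics against the
interpretability of the resolved spectra and maps; the pipeline accepts an
expert override (`--components`). The pipeline evaluates the trace on the
zero-order multiset: the derivative filter's edge rows amplify noise into
one or two spurious variance directions that inflate the tail of the
derivative-space trace.

Initial spectra come from SIMPLISMA purest-pixel selection on the
zero-order data: the purity of pixel $i$ is
$\sigma_i / (\mu_i + \alpha\,\max_j \mu_j)$ with a 10% noise margin
($\alpha = 0.1$) damping low-intensity pixels; selections after the first
are weighted by the determinant of the correlation-around-origin matrix of
the already-selected rows plus the candidate, suppressing near-collinear
picks. The selected zero-order spectra are then derivatized with the same
Savitzky-Golay settings as the data before entering ALS — the ordering
(select on zero-order, then derivatize) is fixed in the code. Note what the
purity statistic does and does not guarantee: it ranks pixels by spectral
"spikiness" relative to mean intensity, so pure pixels win whenever mixing
flattens spectra (balanced mixtures, the usual case); a boundary pixel
dominated by one sharp-spectrum component can outrank a pure pixel of a
flat-spectrum component. ALS refinement recovers from such starts in all
tested conditions.

### Recovering interpretable spectra

Derivative-space component spectra are hard to read, so zero-order spectra
are recovered by projecting the (image-norm normalized) zero-order data onto
the resolved concentrations with the Moore-Penrose pseudoinverse:

$$S^\top = (C^\top C)^{-1} C^\top D_0.$$

For exact bilinear data with full-rank $C$ this is an identity (asserted to
$10^{-8}$); for noisy data it is the least-squares spectrum of each
component. When $C^\top C$ is ill-conditioned a small ridge
($\lambda = 10^{-8}\,\mathrm{tr}(C^\top C)/k$) is added with a warning —
the plain inverse presumes a full-rank $C$ that noisy fits occasionally
violate. Recovered rows are unit-normalized for reporting; the raw solution
is kept as an attribute.

## Preprocessing

Stages run in a fixed order — cosmic rays, baseline, denoising, derivative,
trimming — with both the derivative cube (for decomposition) and the
trimmed zero-order cube (for recovery; deliberately not smoothed after PCA
reconstruction) returned:

1. **Cosmic rays**: a third-order (window-3) running median over pixels in
   raster order, one channel at a time. A guarded variant replaces only
   values deviating from the running median by more than a threshold times a
   robust per-channel noise scale; it is off by default, matching the plain
   reading of a median filter. Regime caveat: any window-3 median replaces a
   value with a neighbour estimate, so its accuracy is bounded by
   pixel-to-pixel signal variation. On spatially oversampled (smooth) data it
   removes essentially all single-channel impulses with sub-percent
   distortion; across sharp region boundaries the replacement error is
   gradient-bounded no matter the variant. The validation quantifies the
   filter in the former regime.
2. **Cluster-adaptive baseline**: pixels are k-means-clustered on
   area-normalized spectra (default 4 clusters, 10 restarts, fixed seed) and
   each pixel's fluorescence background is estimated by asymmetric least
   squares with its cluster's $(\lambda, p)$: minimise
   $\sum_i w_i (y_i - z_i)^2 + \lambda \sum (\Delta^2 z)^2$ with
   $w_i = p$ above the baseline and $1-p$ below, iterated to weight
   stability (Whittaker-style sparse banded solves). Defaults
   $\lambda = 10^5$, $p = 10^{-4}$ for 532 nm data; $\lambda = 10^4$ for the
   more strongly curved 785 nm backgrounds (both within the range used in
   practice for these tissues). Clustering matters exactly because lumen,
   wall and deposits fluoresce differently — the per-cluster parameters let
   stiff baselines coexist with curvy ones.
3. **PCA denoising**: rank-truncated reconstruction of the mean-centred
   cube (the mean spectrum is added back; centring is a convention the
   method sources leave open, and the mean-centred variant keeps the
   truncation orthogonal to the dominant offset). Defaults: 15 components at
   532 nm, 10 at 785 nm.
4. **Derivative**: second-order Savitzky-Golay, window 11, first derivative
   with respect to channel index (the chemometrics convention; a non-uniform
   axis beyond 1% triggers a warning). Edges use the interpolating
   polynomial fit, no wrap-around. Reference spectra use the same filter at
   zeroth order with window 6 rounded up to 7 (a symmetric filter needs an
   odd window) and a warning.
5. **Trimming**: peak-free ranges are dropped — keep 250-1750 and
   2530-3740 cm^-1 at 532 nm, 250-1750 cm^-1 at 785 nm (closed intervals).
6. **Normalization**: reference and recovered spectra are scaled to unit
   2-norm; image blocks optionally by image norm (above). Per-pixel
   normalization is deliberately *not* applied to image data — it would
   rescale each row of $C$ and distort the maps.

## The synthetic scenes

`make_scene()` emulates a transverse tracheid section: an S2 secondary-wall
band, a compound-middle-lamella ring, a lumen, a ray stripe and droplet
deposits, with components assigned to regions (unused regions fall back to
the component of their host region, so small lumens are not punctured by
droplet holes). One 3x3 smoothing pass imitates spatial oversampling while
leaving region cores pure — purest-pixel selection depends on those cores.
Component spectra are built from the package's marker-band table:
pseudo-Voigt peaks (default FWHM 12 cm^-1, 6 for sharp-annotated bands,
30% Lorentzian) with heights by intensity class
(vs 1.0, s 0.7, m 0.4, w 0.15, sh 0.25) — only the ordering is meaningful.
Shoulder (sh) bands ride a stronger neighbour and need not appear as
distinct local maxima, as in measured spectra.

On top of the bilinear signal the generator adds:

* a **fluorescence baseline**: per pixel, a low-order polynomial plus a
  broad decaying exponential whose amplitude depends on the tissue region.
  The exponential's decay constant defaults to 0.8 of the axis span: wood
  autofluorescence varies on the scale of the spectral window, and a
  background much steeper than that falls outside the smoothness class that
  asymmetric least squares with the practical penalty range
  ($\lambda = 10^4$–$10^5$) can track — it would be uncorrectable by the
  method whose use it is meant to exercise.
* **Gaussian noise**, optionally heteroscedastic ($\propto \sqrt{signal}$,
  a shot-noise approximation); `noise_sigma_for_snr()` converts a target
  SNR (RMS signal over sigma) into the noise scale.
* **cosmic-ray spikes**: single-channel impulses at recorded positions,
  amplitudes 10-20x the noise scale by default. Draws are rejected until no
  two impulses share a channel within two raster pixels: cosmic rays are
  independent rare events, and such collisions are a small-cube sampling
  artefact rather than part of the model (a window-3 median cannot, by
  construction, remove two adjacent impulses). Scenes differing only in
  the number of spikes share layout, baseline and noise draws, so a
  spike-free twin of any scene is available for oracle comparisons.
* **absence flags**: a component flagged absent from an image contributes
  exactly zero signal there (its region is reassigned), emulating image
  groups in which a constituent occurs only in some images.

Everything is reproducible bit for bit from a seed.

What the generator does *not* emulate: confocal optics (point-spread
function, depth response), polarization response beyond providing two
distinct cellulose-orientation spectra, photobleaching, detector
nonlinearity, or instrument wavenumber calibration error. Passing tests on
these scenes therefore demonstrate the correctness and robustness of the
*computational* chain under the stated statistical structure — bilinear
mixing, smooth heterogeneous backgrounds, Gaussian noise, impulsive spikes —
not performance against every artefact of real instruments.

## Identification

Recovered spectra are assigned substances by marker-band matching against
the built-in table (per excitation, because the 785 nm setup does not reach
the C-H stretching region and relative intensities differ). Peaks are
detected by topographic prominence (>= 5% of the spectrum maximum, minimum
separation 2 channels) after a light Savitzky-Golay smoothing (window 5)
with parabolic apex refinement — both standard peak-picking devices that
stabilise apex positions under noise. A substance's score is the weighted
fraction of its table bands matched within 8 cm^-1 (roughly 2-3x the
spectral resolution), with class weights vs 3, s 2, m 1, w 0.5, sh 0.5;
ties break by the number of very-strong/strong bands matched, then by total
matches (needed to separate the two cellulose orientations, whose band sets
overlap). Expert assignment in practice weighs context as well; this rule is
a fixed, reproducible proxy. Scores are invariant to spectrum scaling.

A joint PCA of recovered components and reference spectra (extracts,
isolated compounds, in-image averages) gives an overview of which component
resembles which reference: mean-centred PCA on first derivatives of the
unit-normalized combined set, with venetian-blinds cross-validation
(10 splits, blind thickness 2) to indicate the supported number of PCs, and
a sign convention (largest loading positive) that makes scores independent
of sample order. Labels that strain the model (noise-dominated spectra) can
be excluded by name.

## Numerical choices and degenerate inputs

* ALS convergence: relative LOF change below 0.1% (the de-facto default in
  MCR-ALS practice), cap 50 iterations, plus an absolute floor (LOF
  $< 10^{-10}$%) for exact data.
* Rank-deficient $C$ during a spectra update or recovery: ridge fallback
  with a warning (above). Non-finite values abort with an error.
* `estimate_rank` refuses constant matrices; `normalize_l2` names all-zero
  rows; `augment` names the image with a mismatching axis; empty k-means
  clusters re-seed once and then error.
* NNLS uses an unconstrained fast path per pixel (most pixels in pure-ish
  regions have all-positive solutions) and Lawson-Hanson for the rest, with
  a cycling guard.
* The cube CSV container writes numerics with 17 significant digits, so the
  round trip is bit-exact; the binary dialect is RDS serialization.

## Problem sizes used in validation

The shipped validation exercises: exact recovery on a noiseless two-image
32x32 multiset with 600 channels; realistic recovery (region-dependent
baselines, SNR 20, 100 spikes, one absent component) on two 32x32 785 nm
images; rank estimation over 20 seeded replicates of two-image 16x16
multisets; half-step oracle equivalence on instances up to 20x12x3; and
identification over 100 noisy trials per substance and excitation. These
sizes resolve the statistical questions while keeping a full run in a few
minutes on one CPU.

## A worked run

```{r, eval = FALSE}
cfg <- default_config("larch-like")
cfg$simulate$absent <- list(c(2L, 3L))   # flavonoids absent from image 2
state <- run_pipeline(cfg, "run1", seed = 7)
pipeline_report("run1")
glance(state$model)
autoplot(state$model)
plot_maps(state$model$C[1:1024, ], 32, 32)
```

## Known limitations

* Rotational ambiguity is inherent to bilinear unmixing; the package reports
  point estimates only (no feasible-band analysis). Quality metrics against
  ground truth are computed after greedy maximum-|cosine| matching with sign
  resolution, since permutation, scale and (for derivatives) sign are not
  identified.
* The marker-band scoring is position-based; it does not use relative
  intensities beyond the class weights and cannot distinguish substances
  whose band sets coincide within tolerance.
* The correspondence constraint requires the user (or the configuration) to
  declare absences; the package does not infer them from preliminary fits.
* Concentration maps are relative (arbitrary units, 0-1 scaled for export);
  no quantitative calibration is attempted.
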