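#' Generate spatial component layouts mimicking softwood tissue
#'
#' Builds k nonnegative per-pixel abundance maps arranged like a transverse
#' section of a tracheid: an S2 secondary-wall band, a compound-middle-lamella
#' (CML) ring at the cell boundary, a lumen, a ray stripe and droplet deposits.
#' Components are assigned to regions in that order; when fewer components
#' than regions are requested the remaining regions fall back to component 1,
#' so every pixel carries signal. A single smoothing pass mixes region
#' boundaries (as spatial oversampling does) while leaving region cores pure,
#' which is what pixel-based purest-variable selection relies on.
#'
#' @param width,height Grid size in pixels (each >= 8).
#' @param k Number of components (>= 1, <= 5 distinct regions).
#' @param intensity_jitter Relative amplitude of the smooth within-region
#'   intensity variation (0 disables it).
#' @param blur_passes Number of 3x3 smoothing passes at region boundaries.
#' @param absent Integer vector of component indices absent from this scene;
#'   their regions are reassigned to the first non-absent component.
#' @param seed Optional RNG seed for the intensity field.
#' @return List with `maps` (pixels x k, raster order), `region` (per-pixel
#'   region index before fallback) and `region_names`.
#' @export
scene_layout <- function(width, height, k, intensity_jitter = 0.25,
                         blur_passes = 1, absent = integer(0), seed = NULL) {
  if (width < 8 || height < 8) stop("image dims must be at least 8 x 8")
  if (k < 1) stop("k must be >= 1")
  region_names <- c("S2", "CML", "lumen", "ray", "droplets")
  col <- (seq_len(width * height) - 1L) %% width      # 0-based x
  row <- (seq_len(width * height) - 1L) %/% width     # 0-based y

  region <- rep(1L, width * height)                   # S2 by default
  # CML: 2-pixel frame at the cell boundary
  frame <- col <= 1L | col >= width - 2L | row <= 1L | row >= height - 2L
  region[frame] <- 2L
  # lumen: central rectangle
  lx <- c(floor(width / 3), ceiling(2 * width / 3) - 1L)
  ly <- c(floor(height / 3), ceiling(2 * height / 3) - 1L)
  lum <- col >= lx[1] & col <= lx[2] & row >= ly[1] & row <= ly[2]
  region[lum] <- 3L
  # ray: 2-row stripe between lumen and lower wall
  ry <- max(ly[2] + 2L, height - 6L)
  ray <- row >= ry & row <= ry + 1L & !frame
  region[ray] <- 4L
  # droplets: two small discs inside the lumen
  cx <- c(lx[1] + 1L, lx[2] - 1L); cy <- c(ly[1] + 1L, ly[2] - 1L)
  drop <- ((col - cx[1])^2 + (row - cy[1])^2 <= 1.5) |
    ((col - cx[2])^2 + (row - cy[2])^2 <= 1.5)
  region[drop & lum] <- 5L

  # unused regions fall back to the component of the region that hosts them:
  # the ray stripe lies in the wall (S2), droplets are deposits in the lumen
  comp_of_region <- seq_along(region_names)
  if (k < 4L) comp_of_region[4L] <- 1L
  if (k < 5L) comp_of_region[5L] <- comp_of_region[3L]
  comp_of_region[comp_of_region > k] <- 1L
  if (length(absent)) {
    keep <- setdiff(seq_len(k), absent)
    if (!length(keep)) stop("absence flags remove all components")
    comp_of_region[comp_of_region %in% absent] <- keep[1]
  }
  comp <- comp_of_region[region]

  maps <- matrix(0, nrow = width * height, ncol = k)
  maps[cbind(seq_along(comp), comp)] <- 1
  if (intensity_jitter > 0) {
    field <- with_seed(seed, {
      f <- matrix(runif(width * height, -1, 1), height, width)
      for (i in 1:4) f <- blur_once(f)
      f
    })
    f <- as.vector(t(field))
    f <- f / max(abs(f), 1e-12)
    maps <- maps * (1 + intensity_jitter * f)
  }
  if (blur_passes > 0) {
    for (j in seq_len(k)) {
      m <- matrix(maps[, j], height, width, byrow = TRUE)
      for (i in seq_len(blur_passes)) m <- blur_once(m)
      maps[, j] <- as.vector(t(m))
    }
  }
  if (length(absent)) maps[, absent] <- 0
  list(maps = maps, region = region, region_names = region_names)
}

# One 3x3 box-blur pass with edge replication.
blur_once <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- m[c(1, 1:h, h), c(1, 1:w, w)]
  out <- matrix(0, h, w)
  for (dy in 0:2) for (dx in 0:2) {
    out <- out + pad[dy + 1:h, dx + 1:w]
  }
  out / 9
}

#' Specify the fluorescence baseline model of a synthetic scene
#'
#' The per-pixel additive background is a low-order polynomial plus a broad
#' decaying exponential whose amplitude depends on the tissue region, so that
#' cluster-adaptive baseline correction has genuinely heterogeneous
#' backgrounds to resolve.
#'
#' @param amplitude Overall baseline scale in signal units (0 disables).
#' @param region_factors Multiplier per layout region (recycled to 5).
#' @param tau Decay constant of the exponential term, as a fraction of the
#'   axis span. The default (0.8) keeps the background varying on the scale
#'   of the whole spectral window, as wood autofluorescence does; backgrounds
#'   much steeper than this fall outside the smoothness class that asymmetric
#'   least squares with the usual Raman penalty range can track.
#' @param poly Polynomial coefficients (intercept, slope) on the normalized
#'   axis coordinate in [0, 1].
#' @return A list of class `baseline_spec`.
#' @export
baseline_spec <- function(amplitude = 0,
                          region_factors = c(1, 0.4, 1.6, 0.8, 1.2),
                          tau = 0.8, poly = c(0.3, 0.15)) {
  structure(list(amplitude = amplitude,
                 region_factors = rep_len(region_factors, 5L),
                 tau = tau, poly = poly),
            class = "baseline_spec")
}

#' Simulate a hyperspectral Raman image with known ground truth
#'
#' Generates an observed cube following the bilinear mixing model plus a
#' smooth region-dependent fluorescence baseline, additive Gaussian noise
#' (optionally heteroscedastic, approximating shot noise) and single-channel
#' cosmic-ray spikes:
#' `observed = maps %*% spectra + baseline + noise + spikes`.
#'
#' @param spectra k x n_channels matrix of component spectra (rows are
#'   normalized to unit 2-norm and must be nonnegative).
#' @param axis Wavenumber axis matching `ncol(spectra)`.
#' @param width,height Image size in pixels.
#' @param layout Optional precomputed [scene_layout()]; generated when NULL.
#' @param baseline A [baseline_spec()].
#' @param noise_sigma Gaussian noise standard deviation (>= 0), in the same
#'   units as the mixed signal.
#' @param heteroscedastic If TRUE the noise sd scales with sqrt of the local
#'   signal (shot-noise approximation).
#' @param n_spikes Number of cosmic-ray impulses to inject.
#' @param spike_amplitude Spike height in units of `noise_sigma` (or of the
#'   maximum signal when `noise_sigma` is 0).
#' @param excitation,pixel_spacing,label Acquisition metadata.
#' @param absent Component indices generated as exactly absent.
#' @param seed RNG seed; the same seed reproduces the scene bit-for-bit, and
#'   scenes differing only in `n_spikes` share layout, baseline and noise.
#' @return List with `image` (a [spectral_image()]) and `scene` (class
#'   `synthetic_scene`: ground-truth spectra, maps, baseline field, noise
#'   level, spike table, region labels, seed).
#' @export
make_scene <- function(spectra, axis, width = 32, height = 32, layout = NULL,
                       baseline = baseline_spec(0), noise_sigma = 0,
                       heteroscedastic = FALSE, n_spikes = 0,
                       spike_amplitude = 10, excitation = 532,
                       pixel_spacing = 333, label = "synthetic",
                       absent = integer(0), seed = NULL) {
  spectra <- as.matrix(spectra)
  if (any(spectra < 0)) stop("component spectra must be nonnegative")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  k <- nrow(spectra)
  spectra <- spectra / sqrt(rowSums(spectra^2))
  stopifnot(ncol(spectra) == length(axis))
  np <- width * height
  nc <- length(axis)

  with_seed(seed, {
    if (is.null(layout)) {
      layout <- scene_layout(width, height, k, absent = absent,
                             seed = if (is.null(seed)) NULL else seed)
    }
    maps <- layout$maps
    if (ncol(maps) != k) stop("layout has ", ncol(maps), " components, need ", k)
    if (length(absent)) maps[, absent] <- 0
    if (all(colSums(maps) == 0)) stop("layout leaves no pixels with signal")
    clean <- maps %*% spectra

    bl <- matrix(0, np, nc)
    if (baseline$amplitude > 0) {
      t01 <- (axis - min(axis)) / diff(range(axis))
      shape <- baseline$poly[1] + baseline$poly[2] * t01 +
        exp(-t01 / baseline$tau)
      amp <- baseline$amplitude * baseline$region_factors[layout$region]
      bl <- outer(amp, shape)
    }

    noise <- matrix(0, np, nc)
    if (noise_sigma > 0) {
      sdmat <- if (heteroscedastic) {
        ref <- mean(abs(clean))
        noise_sigma * sqrt(1 + pmax(clean, 0) / max(ref, 1e-12))
      } else noise_sigma
      noise <- matrix(rnorm(np * nc), np, nc) * sdmat
    }

    spikes <- tibble::tibble(pixel = integer(0), channel = integer(0),
                             amplitude = numeric(0))
    spk <- matrix(0, np, nc)
    if (n_spikes > 0) {
      # cosmic rays are independent rare events: draws are rejected until no
      # two impulses share a channel within 2 raster pixels (such collisions
      # are a small-cube sampling artifact, not part of the model)
      idx <- integer(0)
      for (tries in 1:50) {
        if (length(idx) >= n_spikes) break
        idx <- unique(c(idx, sample.int(np * nc, n_spikes - length(idx))))
        pix <- ((idx - 1L) %% np) + 1L
        chn <- ((idx - 1L) %/% np) + 1L
        ord <- order(chn, pix)
        drop <- which(diff(chn[ord]) == 0 & diff(pix[ord]) <= 2) + 1L
        if (length(drop)) idx <- idx[-ord[drop]]
      }
      idx <- idx[seq_len(min(n_spikes, length(idx)))]
      amp_unit <- if (noise_sigma > 0) noise_sigma else max(clean)
      amps <- spike_amplitude * amp_unit * runif(n_spikes, 1, 2)
      spk[idx] <- spk[idx] + amps
      spikes <- tibble::tibble(
        pixel = ((idx - 1L) %% np) + 1L,
        channel = ((idx - 1L) %/% np) + 1L,
        amplitude = amps
      )
    }

    cube <- clean + bl + noise + spk
    image <- spectral_image(cube, axis, width, height,
                            excitation = excitation,
                            pixel_spacing = pixel_spacing, label = label,
                            metadata = list(seed = seed))
    scene <- structure(
      list(true_spectra = spectra, true_maps = maps, baseline_field = bl,
           noise_sigma = noise_sigma, spikes = spikes, region = layout$region,
           region_names = layout$region_names, absent = absent,
           axis = axis, width = width, height = height, seed = seed),
      class = "synthetic_scene"
    )
    list(image = image, scene = scene)
  })
}

#' Simulate a multi-image group sharing component spectra
#'
#' Generates several images on a common wavenumber axis from one set of
#' component spectra, with per-image absence flags: a component flagged
#' absent contributes exactly zero signal in that image (its layout region is
#' reassigned), emulating groups of tissue images in which some constituents
#' occur only in part of the images.
#'
#' @param spectra Shared k x n_channels component spectra.
#' @param axis Shared wavenumber axis.
#' @param n_images Number of images in the group.
#' @param absent List of `c(image, component)` pairs, or an n_images x k
#'   binary presence matrix (0 = absent).
#' @param width,height Per-image size (recycled).
#' @param seed Base seed; image i uses `seed + i`.
#' @param ... Passed to [make_scene()] (baseline, noise, spikes, metadata).
#' @return List with `images` (list of [spectral_image()]), `scenes`
#'   (per-image ground truth), `true_C` (stacked ground-truth maps, total
#'   pixels x k), `presence` (n_images x k binary matrix) and `spectra`.
#' @export
make_multiset_scene <- function(spectra, axis, n_images = 2,
                                absent = list(), width = 32, height = 32,
                                seed = NULL, ...) {
  spectra <- as.matrix(spectra)
  k <- nrow(spectra)
  if (is.matrix(absent)) {
    stopifnot(nrow(absent) == n_images, ncol(absent) == k)
    M <- (absent != 0) * 1L
  } else {
    M <- matrix(1L, n_images, k)
    for (p in absent) M[p[1], p[2]] <- 0L
  }
  if (any(rowSums(M) == 0)) stop("an image must contain at least one component")
  width <- rep_len(width, n_images)
  height <- rep_len(height, n_images)
  out <- lapply(seq_len(n_images), function(i) {
    make_scene(spectra, axis, width = width[i], height = height[i],
               absent = which(M[i, ] == 0L),
               seed = if (is.null(seed)) NULL else seed + i,
               label = paste0("image", i), ...)
  })
  list(
    images = lapply(out, `[[`, "image"),
    scenes = lapply(out, `[[`, "scene"),
    true_C = do.call(rbind, lapply(out, function(o) o$scene$true_maps)),
    presence = M,
    spectra = out[[1]]$scene$true_spectra
  )
}

#' Noise level achieving a target signal-to-noise ratio
#'
#' SNR is defined as RMS(clean signal) / sigma over the whole cube.
#'
#' @param maps Pixels x k abundance maps.
#' @param spectra k x channels component spectra.
#' @param snr Target SNR.
#' @return Gaussian noise standard deviation.
#' @export
noise_sigma_for_snr <- function(maps, spectra, snr) {
  clean <- as.matrix(maps) %*% as.matrix(spectra)
  sqrt(mean(clean^2)) / snr
}
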