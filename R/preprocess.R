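#' Remove cosmic-ray spikes with a running median over pixels
#'
#' Cosmic rays hit single detector channels of single pixels. For each
#' wavenumber channel independently, a running median of the given window is
#' applied over pixels in raster-scan order, which removes single-pixel
#' impulses while barely touching the spatially smooth signal. The default
#' window of 3 is a third-order median filter.
#'
#' @param image A [spectral_image()].
#' @param window Odd window length >= 3, in pixels along the raster scan.
#' @param guard_threshold Optional: when set, a pixel value is only replaced
#'   by the running median if it deviates from it by more than
#'   `guard_threshold` times the per-channel median absolute deviation
#'   (outlier-only variant); `NULL` (default) replaces all values.
#' @return The filtered [spectral_image()], same dimensions.
#' @export
remove_cosmic_rays <- function(image, window = 3, guard_threshold = NULL) {
  stopifnot(inherits(image, "spectral_image"))
  if (window %% 2 == 0 || window < 3) stop("window must be odd and >= 3")
  if (window >= n_pixels(image)) stop("window must be smaller than pixel count")
  cube <- image$cube
  out <- cube
  for (j in seq_len(ncol(cube))) {
    med <- runmed(cube[, j], k = window, endrule = "median")
    if (is.null(guard_threshold)) {
      out[, j] <- med
    } else {
      dev <- abs(cube[, j] - med)
      # robust per-channel noise scale from first differences over pixels
      s <- 1.4826 * median(abs(diff(cube[, j]))) / sqrt(2)
      hit <- dev > guard_threshold * max(s, 1e-12)
      out[hit, j] <- med[hit]
    }
  }
  set_cube(image, out)
}

#' Asymmetric least squares baseline of one spectrum
#'
#' Estimates a smooth background below the peaks: the baseline `z` minimizes
#' `sum(w * (y - z)^2) + lambda * sum(diff(z, differences = 2)^2)` with
#' asymmetric weights `w = p` where `y > z` and `1 - p` otherwise, iterated
#' until the weights stabilize. Small `p` pushes the fit under the peaks,
#' estimating the fluorescence background of a Raman spectrum.
#'
#' @param y Numeric intensity vector (length >= 5, finite).
#' @param lambda Smoothness penalty (> 0); larger is stiffer.
#' @param p Asymmetry weight in (0, 1); typical Raman values 1e-4 to 1e-3.
#' @param n_iter Maximum reweighting iterations.
#' @return Numeric baseline vector of the same length.
#' @export
als_baseline <- function(y, lambda, p, n_iter = 10) {
  if (!all(is.finite(y))) stop("input spectrum contains non-finite values")
  n <- length(y)
  if (n < 5) stop("spectrum too short for baseline estimation")
  if (lambda <= 0) stop("lambda must be > 0")
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  DtD <- second_diff_penalty(n)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(n_iter)) {
    M <- Matrix::Diagonal(n, x = w) + lambda * DtD
    z <- as.numeric(Matrix::solve(M, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (max(abs(w_new - w)) < 1e-6) { w <- w_new; break }
    w <- w_new
  }
  z
}

# Cached D2' D2 penalty matrices (pentadiagonal, sparse).
penalty_cache <- new.env(parent = emptyenv())
second_diff_penalty <- function(n) {
  key <- as.character(n)
  if (!is.null(penalty_cache[[key]])) return(penalty_cache[[key]])
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  DtD <- Matrix::crossprod(D)
  penalty_cache[[key]] <- DtD
  DtD
}

#' Baseline parameter set for cluster-adaptive correction
#'
#' @param n_clusters Number of k-means clusters (>= 1).
#' @param lambda Smoothness penalty per cluster (recycled).
#' @param p Asymmetry weight per cluster (recycled), in (0, 0.5).
#' @param n_iter Reweighting iterations per spectrum.
#' @return A list of class `baseline_params`.
#' @export
baseline_params <- function(n_clusters = 4, lambda = 1e5, p = 1e-4,
                            n_iter = 10) {
  lambda <- rep_len(lambda, n_clusters)
  p <- rep_len(p, n_clusters)
  if (any(lambda <= 0)) stop("lambda must be > 0")
  if (any(p <= 0 | p >= 0.5)) stop("p must be in (0, 0.5)")
  structure(list(n_clusters = as.integer(n_clusters), lambda = lambda, p = p,
                 n_iter = n_iter), class = "baseline_params")
}

#' Cluster-adaptive asymmetric least squares baseline correction
#'
#' Wood tissue images show heterogeneous fluorescence backgrounds (lumen,
#' cell wall and deposits fluoresce differently), so a single baseline
#' parameterization rarely fits all pixels. Pixels are first clustered by
#' k-means on their area-normalized spectra; each pixel's baseline is then
#' estimated by [als_baseline()] with its cluster's `(lambda, p)` and
#' subtracted.
#'
#' @param image A [spectral_image()].
#' @param params A [baseline_params()].
#' @param seed RNG seed for k-means (10 restarts).
#' @return List with `image` (corrected), `labels` (per-pixel cluster index)
#'   and `baselines` (pixels x channels matrix), for audit.
#' @export
baseline_correct_adaptive <- function(image, params = baseline_params(),
                                      seed = 1) {
  stopifnot(inherits(image, "spectral_image"), inherits(params, "baseline_params"))
  cube <- image$cube
  np <- nrow(cube)
  if (params$n_clusters > np) stop("more clusters than pixels")
  if (params$n_clusters == 1L) {
    labels <- rep(1L, np)
  } else {
    feat <- cube / pmax(rowSums(abs(cube)), 1e-12)
    km <- with_seed(seed, tryCatch(
      kmeans(feat, centers = params$n_clusters, nstart = 10, iter.max = 50),
      error = function(e) NULL))
    if (is.null(km)) {
      km <- with_seed(seed + 1, kmeans(feat, centers = params$n_clusters,
                                       nstart = 10, iter.max = 50))
    }
    labels <- km$cluster
    if (length(unique(labels)) < params$n_clusters) {
      stop("empty cluster after k-means assignment")
    }
  }
  baselines <- matrix(0, np, ncol(cube))
  for (i in seq_len(np)) {
    cl <- labels[i]
    baselines[i, ] <- als_baseline(cube[i, ], params$lambda[cl], params$p[cl],
                                   params$n_iter)
  }
  list(image = set_cube(image, cube - baselines), labels = labels,
       baselines = baselines)
}

#' PCA denoising by truncated reconstruction
#'
#' Replaces the cube by its rank-`n_pcs` reconstruction from a mean-centered
#' principal component analysis (the column mean spectrum is added back).
#' Typical settings: 15 components for 532 nm images, 10 for the noisier
#' 785 nm images.
#'
#' @param image A [spectral_image()].
#' @param n_pcs Number of principal components to keep.
#' @return Denoised [spectral_image()], same dimensions.
#' @export
denoise_pca <- function(image, n_pcs) {
  stopifnot(inherits(image, "spectral_image"))
  cube <- image$cube
  r <- min(nrow(cube), ncol(cube))
  if (n_pcs < 1 || n_pcs > r) stop("n_pcs must be in [1, ", r, "]")
  mu <- colMeans(cube)
  xc <- sweep(cube, 2, mu)
  sv <- svd(xc, nu = n_pcs, nv = n_pcs)
  rec <- sv$u %*% (diag(sv$d[seq_len(n_pcs)], n_pcs) %*% Matrix::t(sv$v))
  set_cube(image, sweep(as.matrix(rec), 2, mu, `+`))
}

# Sparse channels x channels Savitzky-Golay operator built from the signal
# package's projection matrix: interior rows apply the central filter, edge
# rows the interpolating-polynomial fits (no wrap-around).
sg_operator <- function(n_channels, window, polyorder, deriv = 0) {
  if (window %% 2 == 0) {
    warning("Savitzky-Golay window must be odd; rounding ", window, " up to ",
            window + 1)
    window <- window + 1
  }
  if (window <= polyorder) stop("window must exceed polyorder")
  if (n_channels < window) stop("spectrum shorter than filter window")
  key <- paste(n_channels, window, polyorder, deriv, sep = "|")
  if (!is.null(sg_cache[[key]])) return(sg_cache[[key]])
  F <- unclass(signal::sgolay(p = polyorder, n = window, m = deriv))
  h <- (window - 1L) / 2L
  nc <- n_channels
  # left edge rows 1..h, interior rows h+1..nc-h, right edge rows nc-h+1..nc
  left_i <- rep(1:h, each = window)
  left_j <- rep(1:window, times = h)
  left_v <- as.vector(t(F[1:h, , drop = FALSE]))
  int_rows <- (h + 1L):(nc - h)
  int_i <- rep(int_rows, each = window)
  int_j <- int_i + rep(-h:h, times = length(int_rows))
  int_v <- rep(F[h + 1L, ], times = length(int_rows))
  right_rows <- (nc - h + 1L):nc
  right_i <- rep(right_rows, each = window)
  right_j <- rep((nc - window + 1L):nc, times = h)
  right_v <- as.vector(t(F[(window - h + 1L):window, , drop = FALSE]))
  L <- Matrix::sparseMatrix(i = c(left_i, int_i, right_i),
                            j = c(left_j, int_j, right_j),
                            x = c(left_v, int_v, right_v),
                            dims = c(nc, nc))
  sg_cache[[key]] <- L
  L
}

sg_cache <- new.env(parent = emptyenv())

apply_sg <- function(x, window, polyorder, deriv) {
  if (is.matrix(x)) {
    L <- sg_operator(ncol(x), window, polyorder, deriv)
    as.matrix(x %*% Matrix::t(L))
  } else {
    L <- sg_operator(length(x), window, polyorder, deriv)
    as.numeric(L %*% x)
  }
}

#' Savitzky-Golay first derivative along the wavenumber axis
#'
#' Computes the per-spectrum first derivative with a Savitzky-Golay filter
#' (default second-order polynomial, window 11). The derivative is taken with
#' respect to the channel index, assuming a uniform wavenumber grid (the
#' chemometrics convention); a warning is issued if the grid spacing varies
#' by more than 1%. Edges use the interpolating-polynomial fit.
#'
#' @param x A [spectral_image()], a spectra matrix (rows = spectra) or a
#'   single spectrum.
#' @param window Odd filter window (> polyorder).
#' @param polyorder Polynomial order.
#' @param axis Optional wavenumber axis for the uniformity check (taken from
#'   the image when `x` is a `spectral_image`).
#' @return Same type and shape as `x`, holding first derivatives.
#' @export
derivative_sg <- function(x, window = 11, polyorder = 2, axis = NULL) {
  if (inherits(x, "spectral_image")) {
    check_axis_uniform(x$axis)
    return(set_cube(x, apply_sg(x$cube, window, polyorder, deriv = 1)))
  }
  if (!is.null(axis)) check_axis_uniform(axis)
  apply_sg(x, window, polyorder, deriv = 1)
}

check_axis_uniform <- function(axis) {
  d <- diff(axis)
  if ((max(d) - min(d)) / mean(d) > 0.01) {
    warning("wavenumber grid is non-uniform by > 1%; ",
            "derivative is taken per channel index")
  }
  invisible(TRUE)
}

#' Savitzky-Golay smoothing of a reference spectrum
#'
#' Zeroth-derivative Savitzky-Golay smoothing, used for noisy reference
#' spectra of extracts. Even window sizes are rounded up to the next odd
#' value with a warning, since a symmetric filter requires an odd window.
#'
#' @param y Numeric spectrum (or matrix of row spectra).
#' @param window Window size (default 6, rounded up to 7).
#' @param polyorder Polynomial order (default 2).
#' @return Smoothed spectrum, same shape.
#' @export
smooth_reference <- function(y, window = 6, polyorder = 2) {
  apply_sg(y, window, polyorder, deriv = 0)
}

#' Trim a spectrum or image to informative wavenumber ranges
#'
#' Keeps only channels whose wavenumber falls inside one of the closed
#' intervals, e.g. the defaults used for data reduction: 250-1750 and
#' 2530-3740 cm^-1 at 532 nm excitation, 250-1750 cm^-1 at 785 nm.
#'
#' @param x A [spectral_image()] or a numeric spectrum with `axis` given.
#' @param keep_ranges List (or 2-column matrix) of `(low, high)` intervals in
#'   cm^-1, non-overlapping and ordered.
#' @param axis Wavenumber axis when `x` is not a `spectral_image`.
#' @return Trimmed object; for a bare spectrum, a list `(axis, values)`.
#' @export
trim_ranges <- function(x, keep_ranges, axis = NULL) {
  rng <- if (is.matrix(keep_ranges)) {
    lapply(seq_len(nrow(keep_ranges)), function(i) keep_ranges[i, ])
  } else if (is.list(keep_ranges)) keep_ranges else list(keep_ranges)
  lows <- vapply(rng, `[`, numeric(1), 1)
  highs <- vapply(rng, `[`, numeric(1), 2)
  if (any(highs < lows)) stop("keep_ranges must be (low, high) pairs")
  if (is.unsorted(lows) || any(head(highs, -1) > tail(lows, -1))) {
    stop("keep_ranges must be ordered and non-overlapping")
  }
  keep_fun <- function(a) {
    keep <- rep(FALSE, length(a))
    for (i in seq_along(lows)) keep <- keep | (a >= lows[i] & a <= highs[i])
    keep
  }
  if (inherits(x, "spectral_image")) {
    keep <- keep_fun(x$axis)
    if (!any(keep)) stop("trimming removed all channels")
    x$cube <- x$cube[, keep, drop = FALSE]
    x$axis <- x$axis[keep]
    return(x)
  }
  if (is.null(axis)) stop("axis required for bare spectra")
  keep <- keep_fun(axis)
  if (!any(keep)) stop("trimming removed all channels")
  if (is.matrix(x)) list(axis = axis[keep], values = x[, keep, drop = FALSE])
  else list(axis = axis[keep], values = x[keep])
}

#' Default trim ranges per excitation wavelength
#'
#' @param excitation 532 or 785.
#' @return List of `(low, high)` intervals in cm^-1.
#' @export
default_trim_ranges <- function(excitation) {
  if (excitation == 532) list(c(250, 1750), c(2530, 3740))
  else if (excitation == 785) list(c(250, 1750))
  else stop("excitation must be 532 or 785 nm")
}

#' Normalize row spectra to unit Euclidean length
#'
#' @param x Numeric matrix (rows = spectra) or a single spectrum.
#' @return Same shape, each row with 2-norm 1.
#' @export
normalize_l2 <- function(x) {
  if (!is.matrix(x)) {
    n <- sqrt(sum(x^2))
    if (n == 0) stop("cannot normalize an all-zero spectrum")
    return(x / n)
  }
  norms <- sqrt(rowSums(x^2))
  bad <- which(norms == 0)
  if (length(bad)) {
    stop("cannot normalize all-zero row(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  x / norms
}

#' Preprocessing configuration
#'
#' Bundles the per-image preprocessing parameters. Defaults follow the green
#' (532 nm) setup: window-3 cosmic-ray median, cluster-adaptive baseline at
#' lambda = 1e5 / p = 1e-4, 15 denoising PCs, second-order Savitzky-Golay
#' first derivative with window 11, and trimming to 250-1750 plus
#' 2530-3740 cm^-1.
#'
#' @param median_window Cosmic-ray median window (odd).
#' @param baseline A [baseline_params()] or NULL to skip correction.
#' @param n_denoise_pcs Denoising PCs or NULL to skip.
#' @param sg_window,sg_polyorder Derivative filter settings.
#' @param keep_ranges Trim intervals; NULL keeps the full axis.
#' @param excitation Convenience: 532 or 785 sets `keep_ranges` and
#'   `n_denoise_pcs` defaults.
#' @param seed Seed for the baseline k-means.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(median_window = 3,
                              baseline = baseline_params(),
                              n_denoise_pcs = NULL,
                              sg_window = 11, sg_polyorder = 2,
                              keep_ranges = NULL,
                              excitation = 532, seed = 1) {
  if (is.null(n_denoise_pcs)) {
    n_denoise_pcs <- if (excitation == 785) 10L else 15L
  }
  if (is.null(keep_ranges)) keep_ranges <- default_trim_ranges(excitation)
  if (sg_window <= sg_polyorder) stop("sg_window must exceed sg_polyorder")
  structure(list(median_window = median_window, baseline = baseline,
                 n_denoise_pcs = n_denoise_pcs, sg_window = sg_window,
                 sg_polyorder = sg_polyorder, keep_ranges = keep_ranges,
                 excitation = excitation, seed = seed),
            class = "preprocess_config")
}

#' Run the full preprocessing chain on one image
#'
#' Applies, in fixed order: cosmic-ray removal, cluster-adaptive baseline
#' correction, PCA denoising, Savitzky-Golay first derivative, and spectral
#' trimming. Both the derivative cube (used for the decomposition) and the
#' trimmed zero-order cube (used for spectrum recovery; the zero-order data
#' are kept unsmoothed after PCA reconstruction) are returned.
#'
#' @param image A [spectral_image()].
#' @param config A [preprocess_config()].
#' @return List of class `preprocessed_image` with elements `derivative`,
#'   `zero_order` and `zero_order_predenoise` (all [spectral_image()]; the
#'   last one is trimmed but not PCA-denoised — component-count estimation
#'   uses it, since truncation distorts the singular value trace),
#'   `baseline_labels`, and `params` (the parameters actually applied, for
#'   provenance logging).
#' @export
preprocess_image <- function(image, config = preprocess_config()) {
  stopifnot(inherits(image, "spectral_image"),
            inherits(config, "preprocess_config"))
  img <- remove_cosmic_rays(image, config$median_window)
  labels <- NULL
  if (!is.null(config$baseline)) {
    bc <- baseline_correct_adaptive(img, config$baseline, seed = config$seed)
    img <- bc$image
    labels <- bc$labels
  }
  pre_denoise <- img
  if (!is.null(config$n_denoise_pcs)) {
    n_pcs <- min(config$n_denoise_pcs, nrow(img$cube), ncol(img$cube))
    img <- denoise_pca(img, n_pcs)
  }
  deriv <- derivative_sg(img, config$sg_window, config$sg_polyorder)
  if (!is.null(config$keep_ranges)) {
    deriv <- trim_ranges(deriv, config$keep_ranges)
    zero <- trim_ranges(img, config$keep_ranges)
    pre_denoise <- trim_ranges(pre_denoise, config$keep_ranges)
  } else {
    zero <- img
  }
  structure(
    list(derivative = deriv, zero_order = zero,
         zero_order_predenoise = pre_denoise, baseline_labels = labels,
         params = unclass(config)),
    class = "preprocessed_image"
  )
}
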