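#' Construct a hyperspectral Raman image
#'
#' A `spectral_image` holds a pixel grid of Raman spectra sharing one
#' wavenumber axis, plus acquisition metadata. Pixels are stored row-major
#' (raster-scan order: row by row, left to right), one matrix row per pixel.
#'
#' @param cube Numeric matrix, `width * height` rows (pixels) by
#'   `length(axis)` columns (wavenumber channels).
#' @param axis Strictly monotone numeric vector of Raman shifts (cm^-1).
#' @param width,height Pixel grid dimensions.
#' @param excitation Laser excitation wavelength in nm (e.g. 532 or 785).
#' @param pixel_spacing Pixel spacing in nm.
#' @param label Free-text image label.
#' @param metadata Optional named list merged into the metadata record.
#'
#' @return An object of class `spectral_image`: a list with elements `axis`,
#'   `cube`, `width`, `height` and `metadata`.
#' @export
spectral_image <- function(cube, axis, width, height,
                           excitation = NA_real_, pixel_spacing = NA_real_,
                           label = "", metadata = list()) {
  cube <- as.matrix(cube)
  axis <- as.numeric(axis)
  if (length(axis) < 2L) stop("axis must have at least two points")
  d <- diff(axis)
  if (!(all(d > 0) || all(d < 0))) stop("axis must be strictly monotone")
  if (ncol(cube) != length(axis)) {
    stop(sprintf("cube has %d columns but axis has %d channels",
                 ncol(cube), length(axis)))
  }
  if (nrow(cube) != width * height) {
    stop(sprintf("cube has %d rows but width * height = %d",
                 nrow(cube), width * height))
  }
  if (!all(is.finite(cube))) stop("cube contains non-finite values")
  md <- modifyList(
    list(excitation = excitation, pixel_spacing = pixel_spacing, label = label),
    metadata
  )
  structure(
    list(axis = axis, cube = cube, width = as.integer(width),
         height = as.integer(height), metadata = md),
    class = "spectral_image"
  )
}

#' @export
print.spectral_image <- function(x, ...) {
  cat(sprintf(
    "<spectral_image> %d x %d pixels, %d channels (%.1f-%.1f cm^-1)\n",
    x$width, x$height, length(x$axis), min(x$axis), max(x$axis)
  ))
  cat(sprintf("  excitation: %s nm, pixel spacing: %s nm, label: '%s'\n",
              format(x$metadata$excitation), format(x$metadata$pixel_spacing),
              x$metadata$label))
  invisible(x)
}

#' @export
dim.spectral_image <- function(x) c(x$height, x$width, length(x$axis))

n_pixels <- function(image) nrow(image$cube)

# Replace the cube of an image, keeping geometry and metadata.
set_cube <- function(image, cube, axis = image$axis) {
  image$cube <- cube
  image$axis <- axis
  stopifnot(ncol(cube) == length(axis), nrow(cube) == image$width * image$height)
  image
}

#' Convert a spectral image to a long tibble
#'
#' One row per (pixel, channel). Pixel coordinates are 0-based with `x` the
#' column and `y` the row, origin at the top-left corner.
#'
#' @param x A `spectral_image`.
#' @param ... Unused.
#' @return A tibble with columns `x`, `y`, `wavenumber`, `intensity`.
#' @method as_tibble spectral_image
#' @export
as_tibble.spectral_image <- function(x, ...) {
  np <- n_pixels(x)
  nc <- length(x$axis)
  px <- rep((seq_len(np) - 1L) %% x$width, times = nc)
  py <- rep((seq_len(np) - 1L) %/% x$width, times = nc)
  wn <- rep(x$axis, each = np)
  intens <- as.vector(x$cube)
  tibble::tibble(x = px, y = py, wavenumber = wn, intensity = intens)
}

#' Fold a per-pixel vector into an image matrix
#'
#' @param values Numeric vector of length `width * height` in raster order.
#' @param width,height Grid dimensions.
#' @return A `height` x `width` matrix.
#' @export
fold_map <- function(values, width, height) {
  stopifnot(length(values) == width * height)
  matrix(values, nrow = height, ncol = width, byrow = TRUE)
}

#' Plot per-pixel component maps
#'
#' Renders one or more per-pixel value vectors (e.g. columns of the MCR-ALS
#' concentration matrix C) as raster maps, each scaled to the 0-1 range as is
#' conventional for component intensity figures.
#'
#' @param maps Numeric matrix, pixels x components (raster order), or vector.
#' @param width,height Pixel grid dimensions.
#' @param names Optional component names.
#' @param rescale Scale each map to 0-1 for display (default TRUE).
#' @return A ggplot object.
#' @export
plot_maps <- function(maps, width, height, names = NULL, rescale = TRUE) {
  maps <- as.matrix(maps)
  k <- ncol(maps)
  if (is.null(names)) names <- paste0("C", seq_len(k))
  if (rescale) {
    maps <- apply(maps, 2, function(v) {
      r <- range(v)
      if (diff(r) == 0) rep(0, length(v)) else (v - r[1]) / diff(r)
    })
  }
  df <- do.call(rbind, lapply(seq_len(k), function(j) {
    data.frame(
      x = (seq_len(width * height) - 1L) %% width,
      y = (seq_len(width * height) - 1L) %/% width,
      value = maps[, j], component = names[j]
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~component) +
    ggplot2::theme_minimal()
}
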