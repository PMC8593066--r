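#' Write a hyperspectral cube container
#'
#' Two dialects of a self-describing container are supported and selected by
#' file extension (or `format`):
#' * `csv` — plain-text long format with a commented header: lines starting
#'   with `#` carry the metadata (dims, axis length, excitation, pixel
#'   spacing, label, provenance), followed by columns `x, y, wavenumber,
#'   intensity` (0-based pixel coordinates, x = column, y = row, origin
#'   top-left). Numerics are written with 17 significant digits, so the round
#'   trip is bit-exact for finite doubles.
#' * `rds` — R's binary serialization of the `spectral_image` (lossless).
#'
#' @param image A [spectral_image()].
#' @param path Output path (`.csv` or `.rds`).
#' @param format `"auto"` (by extension), `"csv"` or `"rds"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(image, path, format = c("auto", "csv", "rds")) {
  stopifnot(inherits(image, "spectral_image"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "csv"
  }
  if (format == "rds") {
    saveRDS(image, path)
    return(invisible(path))
  }
  md <- image$metadata
  hdr <- c(
    "# ramanmcr cube v1",
    sprintf("# width: %d", image$width),
    sprintf("# height: %d", image$height),
    sprintf("# channels: %d", length(image$axis)),
    sprintf("# excitation_nm: %s", fmt17(md$excitation %||% NA_real_)),
    sprintf("# pixel_spacing_nm: %s", fmt17(md$pixel_spacing %||% NA_real_)),
    sprintf("# label: %s", md$label %||% ""),
    sprintf("# seed: %s", format(md$seed %||% NA))
  )
  long <- as_tibble.spectral_image(image)
  dt <- data.table::data.table(
    x = long$x, y = long$y,
    wavenumber = fmt17(long$wavenumber),
    intensity = fmt17(long$intensity)
  )
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Read a hyperspectral cube container
#'
#' Counterpart of [write_cube()]; validates that the pixel grid is complete
#' and consistent with the header, naming the first missing pixel otherwise.
#'
#' @param path `.csv` or `.rds` container path.
#' @param format `"auto"`, `"csv"` or `"rds"`.
#' @return A [spectral_image()].
#' @export
read_cube <- function(path, format = c("auto", "csv", "rds")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "csv"
  }
  if (format == "rds") {
    img <- readRDS(path)
    if (!inherits(img, "spectral_image")) stop("not a spectral_image container")
    return(img)
  }
  lines <- readLines(path, n = 20)
  hdr <- grep("^#", lines, value = TRUE)
  if (!length(hdr) || !grepl("ramanmcr cube", hdr[1])) {
    stop("malformed header in ", path, ": missing '# ramanmcr cube' magic (line 1)")
  }
  getv <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(ln)) stop("malformed header: missing '", key, "' (offset ",
                          length(hdr), ")")
    sub(paste0("^# ", key, ": "), "", ln[1])
  }
  width <- as.integer(getv("width"))
  height <- as.integer(getv("height"))
  nchan <- as.integer(getv("channels"))
  excitation <- suppressWarnings(as.numeric(getv("excitation_nm")))
  spacing <- suppressWarnings(as.numeric(getv("pixel_spacing_nm")))
  label <- getv("label")
  dt <- data.table::fread(path, skip = length(hdr), header = TRUE)
  req <- c("x", "y", "wavenumber", "intensity")
  if (!all(req %in% names(dt))) {
    stop("malformed cube CSV: expected columns ", paste(req, collapse = ", "))
  }
  axis <- sort(unique(dt$wavenumber))
  if (length(axis) != nchan) {
    stop(sprintf("inconsistent dims: header says %d channels, data has %d",
                 nchan, length(axis)))
  }
  pix <- dt$y * width + dt$x
  counts <- tabulate(pix + 1L, nbins = width * height)
  if (any(counts < nchan)) {
    miss <- which(counts < nchan)[1] - 1L
    stop(sprintf("missing pixel (x = %d, y = %d): %d of %d channels present",
                 miss %% width, miss %/% width, counts[miss + 1L], nchan))
  }
  if (nrow(dt) != width * height * nchan) {
    stop(sprintf("inconsistent dims: header implies %d rows, found %d",
                 width * height * nchan, nrow(dt)))
  }
  chan <- match(dt$wavenumber, axis)
  cube <- matrix(NA_real_, width * height, nchan)
  cube[cbind(pix + 1L, chan)] <- dt$intensity
  spectral_image(cube, axis, width, height, excitation = excitation,
                 pixel_spacing = spacing, label = label)
}

#' Export per-image component maps
#'
#' Refolds columns of the concentration matrix into per-image maps and writes
#' them as PNG (each component scaled to 0-1, the usual figure convention)
#' and as CSV with the raw values preserved.
#'
#' @param model A `component_model` with a block table.
#' @param dir Output directory (created if needed).
#' @param write_png Also write scaled PNG images (default TRUE).
#' @return Tibble of written files, invisibly.
#' @export
write_component_maps <- function(model, dir, write_png = TRUE) {
  stopifnot(inherits(model, "component_model"))
  if (is.null(model$blocks)) stop("model has no block table")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (i in seq_len(nrow(model$blocks))) {
    b <- model$blocks[i, ]
    Cb <- model$C[b$start:b$end, , drop = FALSE]
    csv <- file.path(dir, sprintf("maps_image%02d.csv", b$image))
    dt <- data.table::data.table(
      x = (seq_len(nrow(Cb)) - 1L) %% b$width,
      y = (seq_len(nrow(Cb)) - 1L) %/% b$width
    )
    for (j in seq_len(ncol(Cb))) dt[[paste0("C", j)]] <- Cb[, j]
    data.table::fwrite(dt, csv)
    files <- c(files, csv)
    if (write_png) {
      for (j in seq_len(ncol(Cb))) {
        v <- Cb[, j]
        r <- range(v)
        v01 <- if (diff(r) > 0) (v - r[1]) / diff(r) else v * 0
        m <- matrix(v01, nrow = b$height, ncol = b$width, byrow = TRUE)
        p <- file.path(dir, sprintf("map_image%02d_C%d.png", b$image, j))
        png::writePNG(m, p)
        files <- c(files, p)
      }
    }
  }
  invisible(tibble::tibble(file = unlist(files)))
}

#' Export resolved component spectra to CSV
#'
#' @param S_T k x channels spectra matrix.
#' @param axis Wavenumber axis.
#' @param path Output CSV (wavenumber column plus one column per component).
#' @param names Optional component names.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(S_T, axis, path, names = NULL) {
  S_T <- as.matrix(S_T)
  if (is.null(names)) names <- paste0("C", seq_len(nrow(S_T)))
  dt <- data.table::data.table(wavenumber = axis)
  for (j in seq_len(nrow(S_T))) dt[[names[j]]] <- S_T[j, ]
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Write/read a correspondence matrix as CSV
#' @param M A `correspondence_matrix`.
#' @param path CSV path.
#' @return `path` invisibly (write) / the matrix (read).
#' @export
write_correspondence_csv <- function(M, path) {
  utils::write.csv(unclass(M), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_correspondence_csv
#' @export
read_correspondence_csv <- function(path) {
  M <- as.matrix(utils::read.csv(path))
  dimnames(M) <- NULL
  storage.mode(M) <- "integer"
  if (!all(M %in% c(0L, 1L))) stop("correspondence matrix must be binary")
  if (any(rowSums(M) == 0)) stop("correspondence matrix has an all-zero row")
  class(M) <- c("correspondence_matrix", class(M))
  M
}
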