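#' Raman marker bands of wood cell-wall polymers and extractives
#'
#' Reference table of marker-band positions and qualitative intensity classes
#' for the substances encountered in softwood tissue: the structural cell-wall
#' polymers (lignin, cellulose in two crystal orientations relative to the
#' incident beam polarization), heartwood extractive classes (lignans,
#' flavonoids, oleoresin constituents: fatty acids, triacylglycerols,
#' crystalline waxes, resin acid types), hydroxycinnamic acids,
#' arabinogalactan, and the CaF2 substrate line. Bands are listed per
#' excitation wavelength because the 785 nm setup does not cover the C-H/O-H
#' stretching region above ~1750 cm^-1 and relative intensities differ.
#'
#' Intensity classes: `vs` very strong, `s` strong, `m` medium, `w` weak,
#' `sh` shoulder. `sharp` marks unusually narrow bands (crystalline waxes,
#' CaF2).
#'
#' @param excitation Optional filter: 532 or 785 (nm).
#' @return A tibble with columns `substance`, `excitation`, `position`
#'   (cm^-1), `intensity_class`, `sharp`.
#' @export
marker_band_table <- function(excitation = NULL) {
  b <- function(substance, excitation, position, class, sharp = FALSE) {
    tibble::tibble(substance = substance, excitation = excitation,
                   position = position, intensity_class = class, sharp = sharp)
  }
  tbl <- rbind(
    # --- 532 nm ---
    b("Lignin", 532, c(3070, 2945, 1660, 1620, 1597, 1457, 1274, 1141),
      c("w", "w", "m", "sh", "vs", "w", "m", "m")),
    b("Cellulose perpendicular", 532, c(2895, 1372, 1336, 1122, 1095, 384),
      c("s", "m", "m", "m", "w", "m")),
    b("Cellulose parallel", 532, c(2902, 1095, 384), c("m", "m", "w")),
    b("Fatty acids", 532, c(2907, 1654, 1461, 1443, 1303),
      c("vs", "m", "m", "m", "w")),
    b("Triacylglycerols", 532, c(2935, 1064), c("vs", "w")),
    b("Crystalline waxes", 532, c(2905, 1297, 1121, 1063, 982),
      c("s", "w", "w", "w", "w"), sharp = c(FALSE, TRUE, TRUE, TRUE, FALSE)),
    b("Resin acids (abietic type)", 532, c(1650, 747, 712), c("m", "w", "m")),
    b("Dehydroabietic acid", 532, c(1612, 747, 708), c("w", "w", "m")),
    b("Isopimaric acid", 532, c(1634, 1433, 712), c("m", "m", "w")),
    b("Oxidized resin acids", 532, c(1710, 1636, 1604), c("w", "s", "s")),
    b("Coumaric acid", 532, c(1636, 1605, 1254, 1204, 1171, 865),
      c("s", "s", "m", "m", "m", "w")),
    b("Ferulic acid", 532, c(3069, 1628, 1608, 1274, 813, 711),
      c("w", "m", "s", "w", "w", "w")),
    b("Ferulates", 532, c(3065, 1680, 1633, 1160, 1125),
      c("w", "w", "s", "w", "w")),
    b("Lignans", 532,
      c(3067, 3020, 2933, 1616, 1605, 1457, 1355, 1276, 1187, 1032, 800, 565, 365),
      c("m", "w", "m", "s", "s", "w", "w", "w", "w", "w", "m", "w", "w")),
    b("CaF2", 532, 323, "s", sharp = TRUE),
    # --- 785 nm ---
    b("Lignin", 785, c(1660, 1597, 1457, 1274, 1141),
      c("m", "s", "w", "m", "m")),
    b("Cellulose perpendicular", 785, c(1372, 1336, 1122, 1095, 384),
      c("m", "m", "m", "m", "s")),
    b("Cellulose parallel", 785, c(1096, 378), c("s", "w")),
    b("Fatty acids", 785, c(1658, 1442, 1305), c("m", "s", "m")),
    b("Triacylglycerols", 785, 1063, "w"),
    b("Crystalline waxes", 785, c(1297, 1130, 1063, 974),
      c("m", "m", "m", "w"), sharp = c(TRUE, TRUE, TRUE, FALSE)),
    b("Resin acids (abietic type)", 785, c(1650, 747, 714), c("m", "w", "w")),
    b("Dehydroabietic acid", 785, c(1615, 747, 711), c("w", "w", "m")),
    b("Isopimaric acid", 785, c(1668, 1639, 1439, 714), c("sh", "m", "m", "m")),
    b("Oxidized resin acids", 785, c(1710, 1636, 1602), c("w", "s", "s")),
    b("Ferulic acid", 785, c(1602, 815), c("s", "w")),
    b("Ferulates", 785, c(1633, 1439, 1163, 1130), c("s", "m", "m", "m")),
    b("Flavonoids", 785,
      c(1640, 1617, 1607, 1365, 1294, 1023, 812, 783, 615, 406),
      c("s", "s", "sh", "m", "m", "m", "w", "m", "w", "m")),
    b("Arabinogalactan", 785, c(1457, 1351, 1262, 1077, 871, 441, 356),
      c("m", "m", "m", "s", "s", "m", "m")),
    b("CaF2", 785, 323, "s", sharp = TRUE)
  )
  tbl <- tibble::as_tibble(tbl)
  validate_band_table(tbl)
  if (!is.null(excitation)) {
    tbl <- tbl[tbl$excitation == excitation, ]
    if (nrow(tbl) == 0L) stop("no bands for excitation ", excitation, " nm")
  }
  tbl
}

band_classes <- c("vs", "s", "m", "w", "sh")

validate_band_table <- function(tbl) {
  stopifnot(all(c("substance", "excitation", "position", "intensity_class")
                %in% names(tbl)))
  if (!all(tbl$intensity_class %in% band_classes)) {
    stop("unknown intensity class: ",
         paste(setdiff(tbl$intensity_class, band_classes), collapse = ", "))
  }
  if (any(tbl$position < 250 | tbl$position > 3740)) {
    stop("band positions must lie within 250-3740 cm^-1")
  }
  invisible(tbl)
}

# Relative peak heights per intensity class. Only the ordering vs > s > m > w
# is meaningful; shoulders are modelled as small satellite peaks.
class_heights <- c(vs = 1.0, s = 0.7, m = 0.4, w = 0.15, sh = 0.25)

# Pseudo-Voigt profile, unit height, FWHM parameterization.
pseudo_voigt <- function(x, center, fwhm, eta = 0.3) {
  u <- (x - center) / fwhm
  g <- exp(-4 * log(2) * u^2)
  l <- 1 / (1 + 4 * u^2)
  eta * l + (1 - eta) * g
}

#' Default wavenumber axes for the two acquisition setups
#'
#' 532 nm spectra span 250-3740 cm^-1 at 3.8 cm^-1 steps; 785 nm spectra span
#' 250-1750 cm^-1 at 2.7 cm^-1 steps (the near-IR setup does not reach the
#' C-H stretching region).
#'
#' @param excitation 532 or 785.
#' @return Numeric wavenumber vector (cm^-1).
#' @export
default_axis <- function(excitation) {
  if (excitation == 532) seq(250, 3740, by = 3.8)
  else if (excitation == 785) seq(250, 1750, by = 2.7)
  else stop("excitation must be 532 or 785 nm")
}

#' Synthesize a component spectrum from its marker bands
#'
#' Builds a nonnegative, unit-norm spectrum for a substance by placing a
#' pseudo-Voigt peak at every marker band listed for it, with relative peak
#' heights set by the qualitative intensity class (vs > s > m > w) and a
#' narrower width for bands annotated as sharp.
#'
#' @param substance Substance name as listed in the band table.
#' @param axis Strictly monotone wavenumber grid (cm^-1).
#' @param excitation 532 or 785 (nm); selects the band set.
#' @param band_table Marker band table (default [marker_band_table()]).
#' @param fwhm Peak FWHM in cm^-1 (default 12; sharp bands use `fwhm_sharp`).
#' @param fwhm_sharp FWHM for sharp-annotated bands (default 6).
#' @param eta Pseudo-Voigt Lorentzian fraction.
#' @return Numeric spectrum of `length(axis)`, nonnegative with unit 2-norm.
#' @export
make_component_spectrum <- function(substance, axis, excitation = 532,
                                    band_table = marker_band_table(),
                                    fwhm = 12, fwhm_sharp = 6, eta = 0.3) {
  if (any(diff(axis) <= 0)) stop("axis must be strictly increasing")
  rows <- band_table[band_table$substance == substance &
                       band_table$excitation == excitation, ]
  if (nrow(rows) == 0L) {
    stop(sprintf("unknown substance '%s' for %d nm excitation",
                 substance, excitation))
  }
  covered <- rows$position >= min(axis) & rows$position <= max(axis)
  if (!any(covered)) {
    stop(sprintf("axis does not cover any marker band of '%s'", substance))
  }
  rows <- rows[covered, ]
  y <- numeric(length(axis))
  for (i in seq_len(nrow(rows))) {
    w <- if (isTRUE(rows$sharp[i])) fwhm_sharp else fwhm
    y <- y + class_heights[[rows$intensity_class[i]]] *
      pseudo_voigt(axis, rows$position[i], w, eta)
  }
  y / sqrt(sum(y^2))
}

#' List substances available for an excitation wavelength
#'
#' @param excitation 532 or 785.
#' @param band_table Marker band table.
#' @return Character vector of substance names.
#' @export
band_substances <- function(excitation = 532, band_table = marker_band_table()) {
  unique(band_table$substance[band_table$excitation == excitation])
}
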