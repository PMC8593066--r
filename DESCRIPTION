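Package: ramanmcr
Title: Multiset MCR-ALS Analysis of Confocal Raman Images of Wood Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping heartwood extractives and cell-wall polymers in
    softwood tissue from confocal Raman hyperspectral images. Implements the
    full chemometric chain: cosmic-ray removal, cluster-adaptive asymmetric
    least squares baseline correction, PCA denoising, Savitzky-Golay
    derivatives, spectral trimming and normalization; column-wise augmented
    multisets with a binary correspondence-among-images constraint; rank
    estimation, SIMPLISMA purest-pixel initial estimates and constrained
    multivariate curve resolution by alternating least squares (MCR-ALS) in
    first-derivative space; pseudoinverse recovery of zero-order component
    spectra; PCA comparison of components against reference spectra; and
    marker-band identification of extractives (lignans, flavonoids,
    oleoresin) and cell-wall polymers. Includes a synthetic-scene generator
    with known ground truth for validation, lossless cube container I/O and
    a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    data.table,
    tibble,
    ggplot2,
    generics,
    png
Suggests:
    testthat (>= 3.0.0),
    pracma,
    tiff,
    withr
Config/testthat/edition: 3
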