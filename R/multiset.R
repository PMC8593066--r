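#' Column-wise augmentation of image groups into a multiset
#'
#' Stacks the pixel spectra of several images that share one wavenumber axis
#' into a single matrix `D` (rows = all pixels image by image, columns =
#' channels), so a joint bilinear decomposition resolves one common set of
#' component spectra across the group. Optionally each image block is divided
#' by its Frobenius norm first, which balances images of different overall
#' intensity (useful for some image groups, unnecessary for others).
#'
#' @param images List of [spectral_image()] with identical axes.
#' @param normalize_by_image_norm Divide every spectrum of image j by the
#'   Frobenius norm of image j's block (default FALSE).
#' @return An object of class `multiset`: list with `D` (total pixels x
#'   channels), `axis`, `blocks` (tibble: `image`, `label`, `start`, `end`,
#'   `width`, `height`; 1-based closed row ranges), `image_norms` (recorded
#'   scaling, 1 when unscaled) and `normalized_by_image_norm`.
#' @export
augment <- function(images, normalize_by_image_norm = FALSE) {
  if (!length(images)) stop("need at least one image")
  stopifnot(all(vapply(images, inherits, logical(1), "spectral_image")))
  axis <- images[[1]]$axis
  for (i in seq_along(images)) {
    if (!isTRUE(all.equal(images[[i]]$axis, axis, tolerance = 0))) {
      lab <- images[[i]]$metadata$label
      stop(sprintf("image %d ('%s') has a mismatching wavenumber axis", i, lab))
    }
  }
  cubes <- lapply(images, `[[`, "cube")
  norms <- vapply(cubes, function(m) sqrt(sum(m^2)), numeric(1))
  if (normalize_by_image_norm) {
    cubes <- Map(`/`, cubes, norms)
  }
  np <- vapply(cubes, nrow, integer(1))
  ends <- cumsum(np)
  starts <- ends - np + 1L
  blocks <- tibble::tibble(
    image = seq_along(images),
    label = vapply(images, function(x) x$metadata$label %||% "", character(1)),
    start = starts, end = ends,
    width = vapply(images, `[[`, integer(1), "width"),
    height = vapply(images, `[[`, integer(1), "height")
  )
  structure(
    list(D = do.call(rbind, cubes), axis = axis, blocks = blocks,
         image_norms = if (normalize_by_image_norm) norms else rep(1, length(images)),
         normalized_by_image_norm = normalize_by_image_norm),
    class = "multiset"
  )
}

#' @export
print.multiset <- function(x, ...) {
  cat(sprintf("<multiset> %d images, %d pixel spectra x %d channels%s\n",
              nrow(x$blocks), nrow(x$D), ncol(x$D),
              if (x$normalized_by_image_norm) " (image-norm scaled)" else ""))
  print(x$blocks)
  invisible(x)
}

#' Split a multiset back into its member images
#'
#' Inverts [augment()]: the recorded image-norm scaling is undone, so the
#' round trip recovers the input images exactly.
#'
#' @param m A `multiset`.
#' @param images Original images (for geometry and metadata).
#' @return List of [spectral_image()].
#' @export
split_multiset <- function(m, images) {
  stopifnot(inherits(m, "multiset"), length(images) == nrow(m$blocks))
  lapply(seq_len(nrow(m$blocks)), function(i) {
    rows <- m$blocks$start[i]:m$blocks$end[i]
    set_cube(images[[i]], m$D[rows, , drop = FALSE] * m$image_norms[i],
             axis = m$axis)
  })
}

#' Build the binary correspondence-among-images matrix
#'
#' One row per image, one column per component; an entry of 0 declares the
#' component absent from that image, and the decomposition then forces the
#' corresponding concentration block to exactly zero.
#'
#' @param n_images,n_components Matrix dimensions.
#' @param absent List of `c(image, component)` pairs (duplicates allowed).
#' @return Binary matrix of class `correspondence_matrix`.
#' @export
build_correspondence <- function(n_images, n_components, absent = list()) {
  M <- matrix(1L, n_images, n_components)
  for (p in absent) {
    i <- p[1]; j <- p[2]
    if (i < 1 || i > n_images || j < 1 || j > n_components) {
      stop(sprintf("absence pair (%d, %d) out of range", i, j))
    }
    M[i, j] <- 0L
  }
  if (any(rowSums(M) == 0)) {
    stop("image ", which(rowSums(M) == 0)[1],
         " has no components left; an image must contain some component")
  }
  class(M) <- c("correspondence_matrix", class(M))
  M
}
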