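#' Recover zero-order component spectra from derivative-space solutions
#'
#' MCR-ALS run on first-derivative data yields derivative-shaped component
#' spectra that are hard to interpret. Interpretable zero-order spectra are
#' recovered by projecting the (image-norm normalized) zero-order data onto
#' the resolved concentration profiles with the Moore-Penrose pseudoinverse:
#' `S_T = solve(t(C) %*% C) %*% t(C) %*% D0`. Rows are then normalized to
#' unit Euclidean length for reporting; the raw least-squares solution is
#' kept in the `"raw"` attribute.
#'
#' @param C Concentration matrix from the derivative-space model (rows x k).
#' @param D0_norm Zero-order multiset matrix (or `multiset`) on the same
#'   pixel rows.
#' @param ridge Force the ridge fallback; by default it engages only when
#'   `t(C) %*% C` is ill-conditioned (with a warning), with
#'   `lambda = 1e-8 * trace(CtC) / k`.
#' @return k x channels matrix of unit-norm recovered spectra, with the
#'   unnormalized solution as attribute `"raw"`.
#' @export
recover_zero_order <- function(C, D0_norm, ridge = FALSE) {
  D0 <- if (inherits(D0_norm, "multiset")) D0_norm$D else as.matrix(D0_norm)
  C <- as.matrix(C)
  if (nrow(C) != nrow(D0)) {
    stop(sprintf("C has %d rows but the zero-order data has %d",
                 nrow(C), nrow(D0)))
  }
  G <- crossprod(C)
  if (ridge || rcond(G) < 1e-10) {
    if (!ridge) warning("ill-conditioned concentration matrix; ridge fallback")
    G <- G + diag(1e-8 * sum(diag(G)) / ncol(C), ncol(C))
  }
  raw <- solve(G, crossprod(C, D0))
  nrm <- sqrt(rowSums(raw^2))
  nrm[nrm == 0] <- 1
  out <- raw / nrm
  attr(out, "raw") <- raw
  out
}

#' Joint PCA of resolved components and reference spectra
#'
#' Places recovered component spectra and reference spectra (extracts, pure
#' compounds, in-image averages) in one score space so related spectra
#' cluster together: mean-centered PCA on the first derivatives of the
#' combined, unit-normalized set, with venetian-blinds cross-validation to
#' indicate how many PCs are supported. Samples known to strain the model
#' (e.g. noise-dominated spectra) can be excluded by label.
#'
#' @param components Matrix of recovered component spectra (rows), or vector.
#' @param refs Matrix of reference spectra on the same axis.
#' @param component_labels,ref_labels Row labels (defaults generated).
#' @param use_derivatives Run the PCA on SG first derivatives (default TRUE).
#' @param sg_window,sg_polyorder Derivative filter settings.
#' @param cv_splits,cv_thickness Venetian-blinds cross-validation: every
#'   sample is assigned to one of `cv_splits` folds in contiguous blocks of
#'   `cv_thickness` (defaults 10 and 2).
#' @param exclusions Character vector of labels to drop before fitting.
#' @param n_pcs Number of PCs to compute (default min(8, n-1)).
#' @return Object of class `pca_result`: `scores`, `loadings`, `explained`
#'   (percent variance per PC), `cv_error` (root-mean PRESS per candidate PC
#'   count), `labels`, `kind` (component/reference flag).
#' @export
pca_components_refs <- function(components, refs,
                                component_labels = NULL, ref_labels = NULL,
                                use_derivatives = TRUE,
                                sg_window = 11, sg_polyorder = 2,
                                cv_splits = 10, cv_thickness = 2,
                                exclusions = character(0), n_pcs = NULL) {
  components <- rbind(components)
  refs <- rbind(refs)
  if (ncol(components) != ncol(refs)) {
    stop("components and references must share the wavenumber axis")
  }
  if (is.null(component_labels)) {
    component_labels <- paste0("C", seq_len(nrow(components)))
  }
  if (is.null(ref_labels)) ref_labels <- paste0("ref", seq_len(nrow(refs)))
  X <- rbind(components, refs)
  labels <- c(component_labels, ref_labels)
  kind <- rep(c("component", "reference"), c(nrow(components), nrow(refs)))
  keep <- !(labels %in% exclusions)
  X <- X[keep, , drop = FALSE]
  labels <- labels[keep]
  kind <- kind[keep]
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples after exclusions")
  X <- normalize_l2(X)
  if (use_derivatives) X <- apply_sg(X, sg_window, sg_polyorder, deriv = 1)
  if (is.null(n_pcs)) n_pcs <- min(8L, n - 1L)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  n_pcs <- min(n_pcs, sum(sv$d > 1e-12))
  V <- sv$v[, seq_len(n_pcs), drop = FALSE]
  # sign convention: largest-magnitude loading positive, so scores do not
  # depend on sample order
  for (j in seq_len(ncol(V))) {
    s <- sign(V[which.max(abs(V[, j])), j])
    if (s < 0) V[, j] <- -V[, j]
  }
  scores <- Xc %*% V
  loadings <- t(V)
  explained <- 100 * sv$d^2 / sum(sv$d^2)

  folds <- (((seq_len(n) - 1L) %/% cv_thickness) %% cv_splits) + 1L
  cv_error <- vapply(seq_len(n_pcs), function(kk) {
    press <- 0
    for (f in unique(folds)) {
      tr <- which(folds != f); te <- which(folds == f)
      if (length(tr) < kk + 1L) return(NA_real_)
      mu_t <- colMeans(X[tr, , drop = FALSE])
      sv_t <- svd(sweep(X[tr, , drop = FALSE], 2, mu_t), nu = 0, nv = kk)
      V <- sv_t$v
      Xe <- sweep(X[te, , drop = FALSE], 2, mu_t)
      press <- press + sum((Xe - Xe %*% V %*% t(V))^2)
    }
    sqrt(press / length(X))
  }, numeric(1))

  structure(
    list(scores = scores, loadings = loadings,
         explained = explained[seq_len(n_pcs)], cv_error = cv_error,
         labels = labels, kind = kind,
         cv = list(splits = cv_splits, thickness = cv_thickness)),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d samples, %d PCs\n", nrow(x$scores),
              ncol(x$scores)))
  cat("  explained (%):", paste(signif(x$explained, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Detect peaks in a spectrum by topographic prominence
#'
#' Local maxima whose prominence (height above the highest saddle connecting
#' them to a taller peak) exceeds `prominence` times the spectrum maximum,
#' separated by at least `min_separation` channels.
#'
#' @param y Numeric spectrum.
#' @param axis Optional wavenumber axis (positions reported on it).
#' @param prominence Relative prominence threshold (default 0.05).
#' @param min_separation Minimum separation in channels (default 2).
#' @param refine Parabolic sub-channel refinement of each apex position
#'   (default TRUE), reducing position jitter from channel quantization.
#' @return Tibble with `channel`, `position`, `height`, `prominence`.
#' @export
find_peaks <- function(y, axis = NULL, prominence = 0.05, min_separation = 2,
                       refine = TRUE) {
  n <- length(y)
  if (is.null(axis)) axis <- seq_len(n)
  if (n < 3) return(tibble::tibble(channel = integer(0), position = numeric(0),
                                   height = numeric(0), prominence = numeric(0)))
  is_max <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(is_max)) {
    return(tibble::tibble(channel = integer(0), position = numeric(0),
                          height = numeric(0), prominence = numeric(0)))
  }
  ymax <- max(y)
  # prominence is bounded by height above the global minimum: cheap screen
  floor_thr <- prominence * max(abs(ymax), 1e-300)
  is_max <- is_max[y[is_max] - min(y) >= floor_thr]
  if (!length(is_max)) {
    return(tibble::tibble(channel = integer(0), position = numeric(0),
                          height = numeric(0), prominence = numeric(0)))
  }
  prom <- vapply(is_max, function(i) {
    h <- y[i]
    left <- y[seq_len(i - 1)]
    higher_l <- which(left > h)
    base_l <- if (length(higher_l)) min(y[(max(higher_l) + 1):(i - 1)], h)
              else min(left, h)
    right <- y[(i + 1):n]
    higher_r <- which(right > h)
    base_r <- if (length(higher_r)) min(y[(i + 1):(i + min(higher_r) - 1)], h)
              else min(right, h)
    h - max(base_l, base_r)
  }, numeric(1))
  keep <- prom >= prominence * max(abs(ymax), 1e-300)
  ch <- is_max[keep]
  pos <- axis[ch]
  if (refine && length(ch)) {
    # parabolic vertex through the apex and its neighbours
    y0 <- y[ch - 1L]; y1 <- y[ch]; y2 <- y[ch + 1L]
    den <- y0 - 2 * y1 + y2
    delta <- ifelse(abs(den) > 1e-300, 0.5 * (y0 - y2) / den, 0)
    delta <- pmin(pmax(delta, -1), 1)
    step <- (axis[pmin(ch + 1L, n)] - axis[pmax(ch - 1L, 1L)]) / 2
    pos <- pos + delta * step
  }
  pk <- tibble::tibble(channel = ch, position = pos,
                       height = y[ch], prominence = prom[keep])
  pk <- pk[order(-pk$height), ]
  sel <- logical(nrow(pk))
  taken <- integer(0)
  for (i in seq_len(nrow(pk))) {
    if (!length(taken) || all(abs(pk$channel[i] - taken) >= min_separation)) {
      sel[i] <- TRUE
      taken <- c(taken, pk$channel[i])
    }
  }
  pk <- pk[sel, ]
  pk[order(pk$channel), ]
}

# Scoring weights per intensity class (ordering-faithful).
class_weights <- c(vs = 3, s = 2, m = 1, w = 0.5, sh = 0.5)

#' Rank candidate substances for a spectrum by marker-band matching
#'
#' Detects peaks in the spectrum and scores every substance of the marker
#' band table (for the given excitation) by the weighted fraction of its
#' bands matched by a detected peak within `tolerance_cm1`; weights reflect
#' the intensity class (vs > s > m > w = sh). Ties are broken first by the
#' number of very-strong/strong bands matched, then by the total number of
#' bands matched. The spectrum is lightly Savitzky-Golay smoothed before peak
#' detection to stabilize apex positions under noise. Matching is invariant
#' to spectrum scaling.
#'
#' @param spectrum Numeric spectrum.
#' @param axis Wavenumber axis (cm^-1).
#' @param excitation 532 or 785; selects the band set.
#' @param band_table Marker band table.
#' @param tolerance_cm1 Match tolerance in cm^-1 (default 8, roughly 2-3x the
#'   spectral resolution).
#' @param prominence,min_separation Peak detection settings ([find_peaks()]).
#' @param smooth_window Savitzky-Golay smoothing window applied before peak
#'   detection (odd; 0 or 1 disables).
#' @return Tibble ranked by score: `substance`, `score`, `n_matched`,
#'   `n_bands`, `strong_matched`, plus list-columns `matched` and `missed`
#'   with band positions. Empty when no peaks are detected.
#' @export
match_bands <- function(spectrum, axis, excitation = 532,
                        band_table = marker_band_table(),
                        tolerance_cm1 = 8, prominence = 0.05,
                        min_separation = 2, smooth_window = 5) {
  tb <- band_table[band_table$excitation == excitation, ]
  if (!nrow(tb)) stop("no marker bands for excitation ", excitation)
  span <- range(axis)
  tb <- tb[tb$position >= span[1] - tolerance_cm1 &
             tb$position <= span[2] + tolerance_cm1, ]
  if (!nrow(tb)) stop("axis does not overlap any marker band")
  if (smooth_window >= 3 && length(spectrum) > smooth_window) {
    spectrum <- apply_sg(spectrum, smooth_window, 2, deriv = 0)
  }
  peaks <- find_peaks(spectrum, axis, prominence, min_separation)
  if (!nrow(peaks)) {
    return(tibble::tibble(substance = character(0), score = numeric(0),
                          n_matched = integer(0), n_bands = integer(0),
                          strong_matched = integer(0),
                          matched = list(), missed = list()))
  }
  res <- lapply(split(tb, tb$substance), function(rows) {
    hit <- vapply(rows$position,
                  function(p) any(abs(peaks$position - p) <= tolerance_cm1),
                  logical(1))
    w <- class_weights[rows$intensity_class]
    tibble::tibble(
      substance = rows$substance[1],
      score = sum(w[hit]) / sum(w),
      n_matched = sum(hit), n_bands = nrow(rows),
      strong_matched = sum(hit & rows$intensity_class %in% c("vs", "s")),
      matched = list(rows$position[hit]),
      missed = list(rows$position[!hit])
    )
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$score, -out$strong_matched, -out$n_matched,
                   out$substance), ]
  tibble::as_tibble(out)
}
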