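#' Cosine similarity between two vectors
#' @param a,b Numeric vectors of equal length.
#' @return Cosine of the angle between `a` and `b`.
#' @export
cosine_similarity <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Match resolved components to ground truth
#'
#' Bilinear decompositions are defined up to component permutation, scale and
#' (for signed derivative spectra) sign. This pairs each true component with
#' a resolved one by greedy maximum absolute cosine between spectra, resolves
#' the sign, and reports spectral cosines and Pearson correlations of the
#' concentration maps for the matched pairs.
#'
#' @param S_est Estimated spectra (k_est x channels).
#' @param S_true True spectra (k_true x channels).
#' @param C_est,C_true Optional concentration matrices (rows x k) for map
#'   correlations; a true map with zero variance (e.g. a component absent
#'   everywhere) yields `NA`.
#' @return Tibble with `truth`, `estimate` (matched index), `cosine` (after
#'   sign resolution) and `map_r`.
#' @export
match_components <- function(S_est, S_true, C_est = NULL, C_true = NULL) {
  S_est <- as.matrix(S_est); S_true <- as.matrix(S_true)
  kt <- nrow(S_true); ke <- nrow(S_est)
  sim <- matrix(0, kt, ke)
  for (i in seq_len(kt)) for (j in seq_len(ke)) {
    sim[i, j] <- cosine_similarity(S_true[i, ], S_est[j, ])
  }
  pairs <- matrix(NA_integer_, kt, 2)
  avail_t <- seq_len(kt); avail_e <- seq_len(ke)
  work <- abs(sim)
  for (s in seq_len(min(kt, ke))) {
    idx <- which(work == max(work[avail_t, avail_e, drop = FALSE])[1] &
                   row(work) %in% avail_t & col(work) %in% avail_e,
                 arr.ind = TRUE)[1, ]
    pairs[idx[1], ] <- c(idx[1], idx[2])
    avail_t <- setdiff(avail_t, idx[1])
    avail_e <- setdiff(avail_e, idx[2])
    work[idx[1], ] <- -Inf
    work[, idx[2]] <- -Inf
  }
  out <- lapply(seq_len(kt), function(i) {
    j <- pairs[i, 2]
    if (is.na(j)) {
      return(tibble::tibble(truth = i, estimate = NA_integer_,
                            cosine = NA_real_, map_r = NA_real_))
    }
    sgn <- sign(sim[i, j])
    if (sgn == 0) sgn <- 1
    map_r <- NA_real_
    if (!is.null(C_est) && !is.null(C_true)) {
      ct <- C_true[, i]; ce <- C_est[, j]
      if (sd(ct) > 0 && sd(ce) > 0) map_r <- stats::cor(ct, ce)
    }
    tibble::tibble(truth = i, estimate = j, cosine = sgn * sim[i, j],
                   map_r = map_r)
  })
  do.call(rbind, out)
}
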