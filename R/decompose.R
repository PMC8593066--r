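#' Estimate the number of components from singular values
#'
#' Computes the singular value spectrum of the multiset matrix and picks the
#' smallest k after which the relative drop between consecutive singular
#' values stays below `drop_threshold` (the "flattening" of the eigenvalue
#' trace). The full trace is returned so the choice can be overridden: in
#' practice the final component count is picked from a combination of fit
#' statistics and the interpretability of the resolved spectra and maps, not
#' from the trace alone.
#'
#' @param m A `multiset` or a numeric matrix.
#' @param drop_threshold Relative successive drop below which the trace
#'   counts as flat (default 0.05).
#' @param window Number of consecutive small drops required (default 3),
#'   guarding against near-equal singular values inside the signal subspace.
#' @param max_k Largest k considered.
#' @return Object of class `rank_estimate`: list with `singular_values`,
#'   `chosen_k`, `criterion_trace` (per-k relative drops) and `user_override`
#'   (NA unless set later).
#' @export
estimate_rank <- function(m, drop_threshold = 0.05, window = 3, max_k = 30) {
  D <- if (inherits(m, "multiset")) m$D else as.matrix(m)
  if (!length(D)) stop("empty multiset")
  if (sd(as.vector(D)) == 0) stop("degenerate multiset: all spectra equal")
  d <- svd(D, nu = 0, nv = 0)$d
  n <- min(length(d), max_k + window + 1L)
  dd <- d[seq_len(n)]
  dd[dd < dd[1] * 1e-10] <- 0          # machine-zero tail counts as flat
  drops <- ifelse(dd[-n] > 0, (dd[-n] - dd[-1]) / dd[-n], 0)
  chosen <- NA_integer_
  for (k in seq_len(min(max_k, n - window))) {
    w <- drops[(k + 1):min(k + window, length(drops))]
    if (all(w < drop_threshold)) { chosen <- k; break }
  }
  if (is.na(chosen)) chosen <- which.max(drops)
  structure(
    list(singular_values = d, chosen_k = as.integer(chosen),
         criterion_trace = drops, user_override = NA_integer_),
    class = "rank_estimate"
  )
}

#' @export
print.rank_estimate <- function(x, ...) {
  cat(sprintf("<rank_estimate> chosen_k = %d\n", x$chosen_k))
  n <- min(10, length(x$singular_values))
  cat("  singular values:", paste(signif(x$singular_values[1:n], 4),
                                  collapse = ", "),
      if (length(x$singular_values) > n) "..." else "", "\n")
  invisible(x)
}

#' SIMPLISMA purest-pixel selection
#'
#' Selects the spectra of the "purest" pixels as initial estimates for the
#' component spectra. The purity of pixel i is `sd_i / (mean_i + alpha *
#' max(mean))`, where the noise margin `alpha` (default 10%) keeps low-mean
#' noisy pixels from dominating. After the first selection, each candidate's
#' purity is weighted by the determinant of the correlation-around-origin
#' matrix of the already-selected rows plus the candidate, which suppresses
#' pixels collinear with earlier picks.
#'
#' @param D0 Zero-order multiset matrix (pixels x channels) or `multiset`.
#' @param n_components Number of pixels to select.
#' @param noise_alpha Noise margin as a fraction of the maximum row mean
#'   (default 0.10).
#' @return List with `indices` (selected pixel rows), `spectra` (their raw
#'   spectra, n_components x channels) and `purity` (first-pass purity of
#'   every row).
#' @export
simplisma <- function(D0, n_components, noise_alpha = 0.10) {
  D0 <- if (inherits(D0, "multiset")) D0$D else as.matrix(D0)
  if (n_components < 1) stop("n_components must be >= 1")
  if (noise_alpha <= 0 || noise_alpha >= 1) stop("noise_alpha must be in (0, 1)")
  if (n_components > min(dim(D0))) {
    warning("n_components exceeds the matrix rank bound; proceeding")
  }
  n <- ncol(D0)
  mu <- rowMeans(D0)
  sg <- sqrt(rowMeans(D0^2) - mu^2)
  off <- noise_alpha * max(mu)
  purity1 <- sg / (mu + off)
  # rows scaled for the correlation-around-origin determinant weights
  lam <- sqrt(mu^2 + (sg + off)^2)
  Z <- D0 / (lam * sqrt(n))
  selected <- integer(0)
  for (s in seq_len(n_components)) {
    if (s == 1) {
      w <- rep(1, nrow(D0))
    } else {
      Zs <- Z[selected, , drop = FALSE]
      Gss <- Zs %*% t(Zs)
      Gsc <- Z %*% t(Zs)                 # candidates x selected
      zz <- rowSums(Z^2)
      # det([[zz, g'],[g, Gss]]) = det(Gss) * (zz - g' Gss^-1 g)
      w <- tryCatch({
        det_ss <- det(Gss)
        inv_ss <- solve(Gss)
        det_ss * pmax(zz - rowSums((Gsc %*% inv_ss) * Gsc), 0)
      }, error = function(e) {
        warning("selected rows are collinear; falling back to plain purity")
        rep(1, nrow(D0))
      })
    }
    score <- purity1 * w
    score[selected] <- -Inf
    selected <- c(selected, which.max(score))
  }
  list(indices = selected, spectra = D0[selected, , drop = FALSE],
       purity = purity1)
}

# --- nonnegative least squares -------------------------------------------

# Lawson-Hanson active-set NNLS in normal-equations space:
# min ||A x - b|| s.t. x >= 0 given AtA (k x k) and Atb (k).
nnls_lh <- function(AtA, Atb, eps = 1e-12) {
  k <- length(Atb)
  P <- logical(k)
  x <- numeric(k)
  w <- Atb
  iter <- 0
  repeat {
    iter <- iter + 1
    if (iter > 30 * (k + 1)) break    # numerical cycling guard
    w_masked <- w
    w_masked[P] <- -Inf
    if (all(w_masked <= eps)) break
    P[which.max(w_masked)] <- TRUE
    repeat {
      s <- numeric(k)
      s[P] <- solve(AtA[P, P, drop = FALSE], Atb[P])
      if (all(s[P] > eps)) { x <- s; break }
      neg <- P & (s <= eps)
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      P[P & (x <= eps)] <- FALSE
      x[!P] <- 0
    }
    w <- Atb - as.numeric(AtA %*% x)
  }
  x
}

# Many right-hand sides sharing A: unconstrained fast path, Lawson-Hanson for
# the columns with negative entries. AtA is k x k, AtB k x m; returns X >= 0.
nnls_normal <- function(AtA, AtB) {
  AtB <- as.matrix(AtB)
  X <- solve(AtA, AtB)
  bad <- which(colSums(X < -1e-12) > 0)
  for (j in bad) X[, j] <- nnls_lh(AtA, AtB[, j])
  X[X < 0] <- 0
  X
}

#' MCR-ALS half-step: concentration update
#'
#' Given component spectra, solves for the concentration matrix that
#' minimizes the residual norm, under nonnegativity (per-row active-set
#' nonnegative least squares, not clipping) and, when a correspondence matrix
#' is supplied, with absent components excluded from the fit of the affected
#' image blocks (exact zeros, and the exact constrained minimizer).
#'
#' @param D Data matrix (rows x channels).
#' @param S_T Component spectra (k x channels).
#' @param nonneg Enforce C >= 0 (default TRUE).
#' @param corr Optional `correspondence_matrix` (images x k).
#' @param blocks Block table (as in a `multiset`), required with `corr`.
#' @return Concentration matrix C (rows x k).
#' @export
mcr_update_c <- function(D, S_T, nonneg = TRUE, corr = NULL, blocks = NULL) {
  k <- nrow(S_T)
  StS <- S_T %*% t(S_T)
  solve_rows <- function(rows, comps) {
    A <- StS[comps, comps, drop = FALSE]
    B <- S_T[comps, , drop = FALSE] %*% t(D[rows, , drop = FALSE])
    if (nonneg) nnls_normal(A, B) else solve(A, B)
  }
  C <- matrix(0, nrow(D), k)
  if (is.null(corr)) {
    C[, ] <- t(solve_rows(seq_len(nrow(D)), seq_len(k)))
  } else {
    if (is.null(blocks)) stop("blocks required with a correspondence matrix")
    if (ncol(corr) != k || nrow(corr) != nrow(blocks)) {
      stop("correspondence matrix dims must be images x components")
    }
    for (i in seq_len(nrow(blocks))) {
      rows <- blocks$start[i]:blocks$end[i]
      comps <- which(corr[i, ] == 1L)
      C[rows, comps] <- t(solve_rows(rows, comps))
    }
  }
  C
}

#' MCR-ALS half-step: spectra update
#'
#' Solves the (by default unconstrained) least squares update of the
#' component spectra given the concentrations. A rank-deficient normal matrix
#' triggers a small ridge fallback with a warning.
#'
#' @param D Data matrix.
#' @param C Concentration matrix (rows x k).
#' @param nonneg Enforce S >= 0 (FALSE by default: derivative-space spectra
#'   are signed).
#' @return Component spectra S_T (k x channels), not normalized.
#' @export
mcr_update_s <- function(D, C, nonneg = FALSE) {
  G <- crossprod(C)
  B <- crossprod(C, D)
  if (nonneg) return(nnls_normal(G, B))
  if (rcond(G) < 1e-12) {
    warning("rank-deficient C during spectra update; using ridge fallback")
    G <- G + diag(1e-8 * sum(diag(G)) / nrow(G), nrow(G))
  }
  solve(G, B)
}

#' Multivariate curve resolution by alternating least squares
#'
#' Fits the bilinear model `D = C %*% S_T + E` by alternating constrained
#' least squares, the standard workflow for hyperspectral image unmixing.
#' Intended use here is on first-derivative multisets (initialized with
#' derivatized purest-pixel spectra): nonnegativity is applied to the
#' concentration maps only, since derivative spectra are signed; resolved
#' spectra are normalized to unit Euclidean norm each iteration (with
#' compensating scaling of C, so the fit is unchanged); and a binary
#' correspondence matrix forces components declared absent from an image to
#' exactly zero concentration there.
#'
#' @param D Data matrix or `multiset` (rows = pixels, columns = channels).
#' @param S0 Initial component spectra (k x channels), e.g. derivatized
#'   SIMPLISMA picks.
#' @param corr Optional `correspondence_matrix` (images x k).
#' @param blocks Block table; taken from `D` when it is a `multiset`.
#' @param nonneg_C Nonnegativity on concentrations (default TRUE).
#' @param nonneg_S Nonnegativity on spectra (default FALSE).
#' @param norm_S Euclidean-normalize spectra rows each iteration.
#' @param tol Convergence: relative change of LOF between iterations
#'   (default 1e-3, i.e. 0.1%).
#' @param max_iter Iteration cap (default 50).
#' @return Object of class `component_model`: `C`, `S_T`, `k`, `lof_percent`,
#'   `r2_percent`, `n_iter`, `converged`, `lof_trace`, `constraint_config`,
#'   `blocks`, `axis`.
#' @export
mcr_als <- function(D, S0, corr = NULL, blocks = NULL, nonneg_C = TRUE,
                    nonneg_S = FALSE, norm_S = TRUE, tol = 1e-3,
                    max_iter = 50) {
  axis <- NULL
  if (inherits(D, "multiset")) {
    if (is.null(blocks)) blocks <- D$blocks
    axis <- D$axis
    D <- D$D
  }
  S_T <- as.matrix(S0)
  if (ncol(S_T) != ncol(D)) stop("S0 channel count must match D")
  k <- nrow(S_T)
  if (!is.null(corr)) {
    if (is.null(blocks)) stop("correspondence constraint requires blocks")
    if (nrow(corr) != nrow(blocks) || ncol(corr) != k) {
      stop("correspondence matrix must be images x components")
    }
  }
  S_T <- S_T / sqrt(rowSums(S_T^2))
  ssd <- sum(D^2)
  if (ssd == 0) stop("all-zero data matrix")
  lof_trace <- numeric(0)
  lof_prev <- Inf
  converged <- FALSE
  it <- 0
  C <- NULL
  while (it < max_iter) {
    it <- it + 1
    C <- mcr_update_c(D, S_T, nonneg = nonneg_C, corr = corr, blocks = blocks)
    S_T <- mcr_update_s(D, C, nonneg = nonneg_S)
    if (!all(is.finite(S_T)) || !all(is.finite(C))) {
      stop("non-finite values during ALS; aborting")
    }
    lof <- 100 * sqrt(sum((D - C %*% S_T)^2) / ssd)
    if (norm_S) {
      nrm <- sqrt(rowSums(S_T^2))
      nrm[nrm == 0] <- 1
      S_T <- S_T / nrm
      C <- C * rep(nrm, each = nrow(C))   # product C %*% S_T unchanged
    }
    lof_trace <- c(lof_trace, lof)
    if (is.finite(lof_prev) &&
        abs(lof_prev - lof) / max(lof_prev, 1e-12) < tol) {
      converged <- TRUE
      break
    }
    if (lof < 1e-10) { converged <- TRUE; break }
    lof_prev <- lof
  }
  stats <- fit_stats(D, C, S_T)
  structure(
    list(C = C, S_T = S_T, k = k,
         lof_percent = stats[["lof_percent"]],
         r2_percent = stats[["r2_percent"]],
         n_iter = it, converged = converged, lof_trace = lof_trace,
         constraint_config = list(nonneg_C = nonneg_C, nonneg_S = nonneg_S,
                                  norm_S = norm_S, correspondence = corr,
                                  tol = tol, max_iter = max_iter),
         blocks = blocks, axis = axis),
    class = "component_model"
  )
}

#' Lack of fit and explained variation of a bilinear model
#'
#' `LOF = 100 * sqrt(sum(E^2) / sum(D^2))` and
#' `R2 = 100 * (1 - sum(E^2) / sum(D^2))` with `E = D - C %*% S_T`, so the
#' identity `R2 = 100 - LOF^2 / 100` always holds.
#'
#' @param D Data matrix.
#' @param C Concentration matrix.
#' @param S_T Component spectra.
#' @return Named numeric vector `(lof_percent, r2_percent)`.
#' @export
fit_stats <- function(D, C, S_T) {
  if (sum(D^2) == 0) stop("all-zero data matrix")
  ratio <- sum((D - C %*% S_T)^2) / sum(D^2)
  c(lof_percent = 100 * sqrt(ratio), r2_percent = 100 * (1 - ratio))
}

#' @export
print.component_model <- function(x, ...) {
  cat(sprintf(
    "<component_model> k = %d, %d pixels x %d channels\n", x$k, nrow(x$C),
    ncol(x$S_T)))
  cat(sprintf("  LOF = %.4g %%, R2 = %.4f %%, %d iterations (%s)\n",
              x$lof_percent, x$r2_percent, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
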