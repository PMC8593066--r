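# Shared fixtures, generated in code: a short wavenumber axis and small
# well-separated synthetic component spectra for fast unit tests.

tiny_axis <- function(n = 120, from = 400, to = 1700) {
  seq(from, to, length.out = n)
}

# k Gaussian-peak spectra with disjoint dominant peaks, unit 2-norm.
tiny_spectra <- function(k = 3, axis = tiny_axis()) {
  centers <- seq(min(axis) + 100, max(axis) - 100, length.out = k)
  sp <- t(vapply(seq_len(k), function(j) {
    y <- exp(-((axis - centers[j]) / 25)^2) +
      0.4 * exp(-((axis - centers[j] - 180) / 18)^2)
    y / sqrt(sum(y^2))
  }, numeric(length(axis))))
  sp
}

tiny_scene <- function(k = 3, width = 12, height = 12, axis = tiny_axis(),
                       seed = 42, ...) {
  make_scene(tiny_spectra(k, axis), axis, width = width, height = height,
             seed = seed, ...)
}

# Dense brute-force ALS baseline oracle: iterated weighted ridge system
# solved with base solve() on the dense penalty matrix.
dense_als_oracle <- function(y, lambda, p, n_iter = 10) {
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  P <- lambda * t(D) %*% D
  w <- rep(1, n)
  z <- y
  for (it in seq_len(n_iter)) {
    z <- solve(diag(w) + P, w * y)
    w_new <- ifelse(y > z, p, 1 - p)
    if (max(abs(w_new - w)) < 1e-6) { w <- w_new; break }
    w <- w_new
  }
  z
}
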