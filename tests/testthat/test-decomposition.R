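# Random bilinear instances with nonnegative C and unit-norm spectra.
random_bilinear <- function(n_rows = 200, k = 5, n_chan = 120, seed = 1,
                            snr = Inf) {
  set.seed(seed)
  C <- matrix(stats::rgamma(n_rows * k, shape = 2), n_rows, k)
  S <- tiny_spectra(k, tiny_axis(n_chan))
  D <- C %*% S
  if (is.finite(snr)) {
    D <- D + matrix(rnorm(length(D), sd = sqrt(mean(D^2)) / snr), nrow(D))
  }
  list(D = D, C = C, S = S)
}

test_that("rank estimation recovers the exact rank of noiseless data", {
  for (k in c(3, 5)) {
    inst <- random_bilinear(k = k, seed = k)
    est <- estimate_rank(inst$D)
    expect_equal(est$chosen_k, k)
    expect_true(all(diff(est$singular_values) <= 1e-8))
    expect_lt(est$singular_values[k + 1] / est$singular_values[1], 1e-10)
  }
  expect_error(estimate_rank(matrix(1, 10, 5)), "degenerate")
})

test_that("rank estimation stays within 1 of truth at SNR 20", {
  inst <- random_bilinear(k = 5, seed = 2, snr = 20)
  est <- estimate_rank(inst$D)
  expect_true(est$chosen_k %in% 4:6)
  expect_gte(length(est$criterion_trace), est$chosen_k)
})

test_that("simplisma finds pure pixels and matches the purity brute force", {
  # pure rows plus balanced mixtures: the regime where the purity statistic
  # provably ranks pure spectra first
  axis <- tiny_axis(200)
  sp <- tiny_spectra(3, axis)
  set.seed(3)
  w <- matrix(runif(150 * 3, 0.25, 0.75), 150, 3)
  w <- w / rowSums(w)
  D <- rbind(w %*% sp, 1.3 * sp, 0.8 * sp)
  sel <- simplisma(D, 3)
  sims <- vapply(1:3, function(j) {
    max(vapply(1:3, function(i)
      cosine_similarity(sel$spectra[i, ], sp[j, ]), numeric(1)))
  }, numeric(1))
  expect_true(all(sims >= 0.999))

  # first selected index maximizes sd / (mean + alpha * max(mean))
  alpha <- 0.1
  mu <- rowMeans(D)
  sg <- apply(D, 1, function(r) sqrt(mean(r^2) - mean(r)^2))
  brute <- which.max(sg / (mu + alpha * max(mu)))
  expect_equal(sel$indices[1], brute)

  warns <- testthat::capture_warnings(sel_over <- simplisma(D[1:4, ], 5))
  expect_true(any(grepl("rank", warns)))
  expect_length(sel_over$indices, 5)
  expect_error(simplisma(D, 2, noise_alpha = 2), "noise_alpha")
})

test_that("constrained C updates match a per-row Lawson-Hanson oracle", {
  skip_if_not_installed("pracma")
  for (seed in 1:3) {
    set.seed(seed)
    S <- matrix(rnorm(3 * 12), 3, 12)       # signed, derivative-like
    D <- matrix(rnorm(20 * 12), 20, 12)
    C <- mcr_update_c(D, S, nonneg = TRUE)
    oracle <- t(apply(D, 1, function(d) pracma::lsqnonneg(t(S), d)$x))
    expect_equal(C, oracle, tolerance = 1e-8)
    # unconstrained update equals ordinary least squares
    C2 <- mcr_update_c(D, S, nonneg = FALSE)
    expect_equal(C2, t(solve(S %*% t(S), S %*% t(D))), tolerance = 1e-10)
  }
})

test_that("correspondence constraint is the exact block-restricted solution", {
  skip_if_not_installed("pracma")
  set.seed(9)
  S <- matrix(rnorm(3 * 12), 3, 12)
  D <- matrix(abs(rnorm(20 * 12)), 20, 12)
  blocks <- tibble::tibble(image = 1:2, label = c("a", "b"),
                           start = c(1L, 11L), end = c(10L, 20L),
                           width = 5L, height = 2L)
  corr <- build_correspondence(2, 3, list(c(2L, 3L)))
  C <- mcr_update_c(D, S, corr = corr, blocks = blocks)
  expect_true(all(C[11:20, 3] == 0))
  oracle2 <- t(apply(D[11:20, ], 1,
                     function(d) pracma::lsqnonneg(t(S[1:2, ]), d)$x))
  expect_equal(C[11:20, 1:2], oracle2, tolerance = 1e-8)
  oracle1 <- t(apply(D[1:10, ], 1, function(d) pracma::lsqnonneg(t(S), d)$x))
  expect_equal(C[1:10, ], oracle1, tolerance = 1e-8)
})

test_that("S updates solve the normal equations with ridge fallback", {
  set.seed(4)
  C <- matrix(stats::rgamma(40 * 3, 2), 40, 3)
  D <- matrix(rnorm(40 * 15), 40, 15)
  S <- mcr_update_s(D, C)
  expect_equal(S, solve(crossprod(C), crossprod(C, D)), tolerance = 1e-10)
  C_def <- cbind(C[, 1], C[, 1], C[, 2])    # rank-deficient
  expect_warning(S2 <- mcr_update_s(D, C_def), "ridge")
  expect_true(all(is.finite(S2)))
})

test_that("mcr_als is a fixed point on exact data initialized at the truth", {
  inst <- random_bilinear(n_rows = 120, k = 3, seed = 5)
  fit <- mcr_als(inst$D, inst$S, max_iter = 5)
  expect_lt(fit$lof_percent, 1e-6)
  expect_true(fit$converged)
  expect_lte(fit$n_iter, 2)
})

test_that("mcr_als recovers seeded noisy components after matching", {
  inst <- random_bilinear(n_rows = 300, k = 3, seed = 6, snr = 20)
  sel <- simplisma(inst$D, 3)
  fit <- mcr_als(inst$D, sel$spectra)
  mm <- match_components(fit$S_T, inst$S, C_est = fit$C, C_true = inst$C)
  expect_true(all(mm$cosine >= 0.95))
  expect_true(all(mm$map_r >= 0.9))
})

test_that("model invariants hold exactly on exit", {
  inst <- random_bilinear(n_rows = 80, k = 3, seed = 7, snr = 30)
  blocks <- tibble::tibble(image = 1:2, label = c("a", "b"),
                           start = c(1L, 41L), end = c(40L, 80L),
                           width = 8L, height = 5L)
  corr <- build_correspondence(2, 3, list(c(2L, 2L)))
  fit <- mcr_als(inst$D, inst$S, corr = corr, blocks = blocks)
  expect_true(all(fit$C >= 0))                            # exact nonnegativity
  expect_equal(rowSums(fit$S_T^2), rep(1, 3), tolerance = 1e-12)
  expect_true(all(fit$C[41:80, 2] == 0))                  # exact zeros
  expect_gte(fit$lof_percent, 0)
  expect_lte(fit$r2_percent, 100)
})

test_that("LOF is non-increasing across unconstrained iterations", {
  inst <- random_bilinear(n_rows = 100, k = 4, seed = 8, snr = 10)
  set.seed(1)
  S0 <- inst$S + matrix(rnorm(length(inst$S), sd = 0.05), nrow(inst$S))
  fit <- mcr_als(inst$D, S0, nonneg_C = FALSE, tol = 1e-12, max_iter = 20)
  expect_true(all(diff(fit$lof_trace) <= 1e-9))
  # with constraints the final LOF cannot exceed the first iterate
  fitc <- mcr_als(inst$D, S0, nonneg_C = TRUE, tol = 1e-12, max_iter = 20)
  expect_lte(fitc$lof_trace[length(fitc$lof_trace)], fitc$lof_trace[1] + 1e-9)
})

test_that("fit statistics follow their algebraic definitions", {
  inst <- random_bilinear(n_rows = 50, k = 2, seed = 9)
  fs <- fit_stats(inst$D, inst$C, inst$S)
  expect_equal(unname(fs), c(0, 100), tolerance = 1e-10)

  # residual with sum(E^2) = 0.01 * sum(data^2) gives LOF 10, R2 99
  C1 <- matrix(1, 10, 1); S1 <- matrix(1, 1, 10)
  model <- C1 %*% S1
  E <- matrix(0, 10, 10)
  # residual orthogonal to the model (Frobenius), scaled to 1% of data energy
  e <- sqrt(sum(model^2) * 0.01 / 0.99)
  E[1, 1] <- e / sqrt(2); E[1, 2] <- -e / sqrt(2)
  fs2 <- fit_stats(model + E, C1, S1)
  expect_equal(unname(fs2[1]), 10, tolerance = 1e-8)
  expect_equal(unname(fs2[2]), 99, tolerance = 1e-8)

  set.seed(10)
  for (i in 1:5) {
    Dr <- matrix(rnorm(100), 10, 10)
    Cr <- matrix(rnorm(20), 10, 2); Sr <- matrix(rnorm(20), 2, 10)
    f <- fit_stats(Dr, Cr, Sr)
    expect_equal(unname(f[2]), 100 - unname(f[1])^2 / 100, tolerance = 1e-8)
  }
  expect_error(fit_stats(matrix(0, 5, 5), C1[1:5, , drop = FALSE],
                         S1[, 1:5, drop = FALSE]), "zero")
})
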