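test_that("cosmic-ray median filter removes impulses and keeps constants", {
  axis <- tiny_axis(60)
  cube <- matrix(5, 100, 60)
  img <- spectral_image(cube, axis, 10, 10)
  expect_equal(remove_cosmic_rays(img)$cube, cube)

  sc <- tiny_scene(noise_sigma = 0, n_spikes = 0, seed = 1)
  img <- sc$image
  spiked <- img
  spiked$cube[50, 30] <- spiked$cube[50, 30] + 10
  out <- remove_cosmic_rays(spiked)
  med <- median(spiked$cube[49:51, 30])
  expect_equal(out$cube[50, 30], med)
  # other channels of that pixel equal the plain-median result of clean data
  clean_out <- remove_cosmic_rays(img)
  expect_equal(out$cube[50, -30], clean_out$cube[50, -30])

  expect_error(remove_cosmic_rays(img, window = 4), "odd")
  expect_error(remove_cosmic_rays(img, window = 1001), "pixel count")
})

test_that("guarded cosmic-ray variant only touches outliers", {
  # homogeneous field: deviations from the running median are noise except at
  # the spikes, so the guard isolates them
  axis <- tiny_axis()
  lay <- scene_layout(12, 12, 1, intensity_jitter = 0)
  sc <- make_scene(tiny_spectra(1, axis), axis, width = 12, height = 12,
                   layout = lay, noise_sigma = 0.02, n_spikes = 30, seed = 3,
                   spike_amplitude = 12)
  out <- remove_cosmic_rays(sc$image, guard_threshold = 6)
  changed <- which(out$cube != sc$image$cube, arr.ind = TRUE)
  sp <- sc$scene$spikes
  expect_true(all(paste(sp$pixel, sp$channel) %in%
                    paste(changed[, 1], changed[, 2])))
  expect_lt(nrow(changed), 3 * nrow(sp))
})

test_that("als_baseline reproduces a straight line with symmetric weights", {
  y <- seq(2, 8, length.out = 100)
  z <- als_baseline(y, lambda = 1e5, p = 0.5)
  expect_equal(z, y, tolerance = 1e-8)
})

test_that("als_baseline matches a dense brute-force solve and hugs a ramp", {
  n <- 150
  ramp <- seq(0, 20, length.out = n)
  peak <- 100 * exp(-4 * log(2) * ((seq_len(n) - 75) / 12)^2)
  y <- ramp + peak
  z <- als_baseline(y, lambda = 1e5, p = 1e-4)
  oracle <- dense_als_oracle(y, lambda = 1e5, p = 1e-4)
  expect_equal(z, oracle, tolerance = 1e-8)
  expect_lt(max(abs(z - ramp)), 5)          # < 5% of peak height

  set.seed(4)
  y2 <- ramp + peak + rnorm(n, sd = 0.5)
  expect_equal(als_baseline(y2, 1e4, 3e-4),
               dense_als_oracle(y2, 1e4, 3e-4), tolerance = 1e-8)
  expect_error(als_baseline(c(y, NA), 1e5, 1e-4), "finite")
  expect_error(als_baseline(y, -1, 1e-4), "lambda")
  expect_error(als_baseline(y, 1e5, 1.5), "p must")
})

test_that("baseline parameterizations from practice are accepted", {
  expect_s3_class(baseline_params(4, lambda = 1e5, p = 2e-4), "baseline_params")
  expect_s3_class(baseline_params(3, lambda = c(1e4, 5e4, 1e5),
                                  p = c(1e-4, 3e-4, 6e-4)), "baseline_params")
  expect_error(baseline_params(2, lambda = 0), "lambda")
  expect_error(baseline_params(2, p = 0.7), "p must")
})

test_that("adaptive correction with one cluster equals plain ALS", {
  sc <- tiny_scene(k = 2, width = 8, height = 8, seed = 2,
                   baseline = baseline_spec(0.8), noise_sigma = 0.01)
  bc <- baseline_correct_adaptive(sc$image, baseline_params(1, 1e4, 1e-4))
  direct <- t(apply(sc$image$cube, 1, als_baseline, lambda = 1e4, p = 1e-4))
  expect_equal(bc$baselines, direct, tolerance = 1e-10)
  expect_true(all(bc$labels == 1L))
})

test_that("k-means clusters recover region structure of the baseline field", {
  # a genuine two-region scene: one component everywhere, baseline amplitude
  # high in the lumen and low elsewhere
  sc <- tiny_scene(k = 1, width = 12, height = 12, seed = 6,
                   baseline = baseline_spec(2, region_factors = c(0.2, 0.2, 3, 0.2, 0.2)),
                   noise_sigma = 0.005)
  bc <- baseline_correct_adaptive(sc$image, baseline_params(2, 1e4, 1e-4),
                                  seed = 1)
  lumen <- sc$scene$region == 3
  # dominant label inside the lumen differs from outside
  lab_in <- as.integer(names(which.max(table(bc$labels[lumen]))))
  lab_out <- as.integer(names(which.max(table(bc$labels[!lumen]))))
  expect_false(lab_in == lab_out)
  agree <- mean((bc$labels == lab_in) == lumen)
  expect_gt(agree, 0.9)
})

test_that("PCA denoising is exact on low-rank data and reduces noise", {
  axis <- tiny_axis(80)
  u <- matrix(runif(64), 64, 1); v <- matrix(runif(80), 1, 80)
  img <- spectral_image(u %*% v, axis, 8, 8)
  expect_equal(denoise_pca(img, 1)$cube, u %*% v, tolerance = 1e-10)

  sp <- tiny_spectra(3, axis)
  sc <- make_scene(sp, axis, width = 10, height = 10, seed = 8,
                   noise_sigma = 0.02)
  clean <- sc$scene$true_maps %*% sp
  den <- denoise_pca(sc$image, 3)
  expect_lt(mean((den$cube - clean)^2), mean((sc$image$cube - clean)^2))
  # matches a direct truncated-SVD oracle
  mu <- colMeans(sc$image$cube)
  xc <- sweep(sc$image$cube, 2, mu)
  svd3 <- svd(xc)
  rec <- svd3$u[, 1:3] %*% diag(svd3$d[1:3]) %*% t(svd3$v[, 1:3])
  expect_equal(den$cube, sweep(rec, 2, mu, `+`), tolerance = 1e-8)
  expect_error(denoise_pca(img, 0), "n_pcs")
  expect_error(denoise_pca(img, 100), "n_pcs")
})

test_that("SG derivative reproduces polynomial slopes and scales linearly", {
  y <- rep(3, 50)
  expect_equal(derivative_sg(y, 11, 2), rep(0, 50), tolerance = 1e-12)
  m <- 2.5
  lin <- m * seq_len(60)
  d <- derivative_sg(lin, 11, 2)
  expect_equal(d[6:55], rep(m, 50), tolerance = 1e-10)
  set.seed(1)
  r <- cumsum(rnorm(80))
  expect_equal(derivative_sg(7 * r, 11, 2), 7 * derivative_sg(r, 11, 2),
               tolerance = 1e-10)
  expect_error(derivative_sg(r[1:5], 11, 2), "shorter")
  expect_warning(derivative_sg(r, axis = c(1:40, 45 + 2 * (1:40))),
                 "non-uniform")
})

test_that("reference smoothing rounds even windows up and reduces variance", {
  set.seed(2)
  y <- rnorm(200)
  expect_warning(s <- smooth_reference(y, window = 6, polyorder = 2), "odd")
  expect_lt(var(s), var(y))
  expect_equal(suppressWarnings(smooth_reference(rep(1, 50), 6, 2)),
               rep(1, 50), tolerance = 1e-12)
})

test_that("trim_ranges keeps closed intervals and validates input", {
  axis <- default_axis(532)
  img <- spectral_image(matrix(1, 4, length(axis)), axis, 2, 2)
  tr <- trim_ranges(img, default_trim_ranges(532))
  expect_true(all((tr$axis >= 250 & tr$axis <= 1750) |
                    (tr$axis >= 2530 & tr$axis <= 3740)))
  expect_lt(length(tr$axis), length(axis))
  # 785 default is a single range
  a785 <- default_axis(785)
  img785 <- spectral_image(matrix(1, 4, length(a785)), a785, 2, 2)
  tr785 <- trim_ranges(img785, default_trim_ranges(785))
  expect_equal(tr785$axis, a785)          # identity: axis already inside
  expect_error(trim_ranges(img, list(c(5000, 6000))), "all channels")
  expect_error(trim_ranges(img, list(c(300, 800), c(700, 900))),
               "non-overlapping")
})

test_that("normalize_l2 produces unit rows, is scale-invariant and idempotent", {
  set.seed(3)
  x <- matrix(abs(rnorm(50)), 5, 10)
  n1 <- normalize_l2(x)
  expect_equal(sqrt(rowSums(n1^2)), rep(1, 5), tolerance = 1e-12)
  expect_equal(normalize_l2(7 * x), n1, tolerance = 1e-12)
  expect_equal(normalize_l2(n1), n1, tolerance = 1e-12)
  x2 <- rbind(x[1, ] * 3, x[1, ])
  n2 <- normalize_l2(x2)
  expect_equal(n2[1, ], n2[2, ], tolerance = 1e-12)
  x[2, ] <- 0
  expect_error(normalize_l2(x), "row")
})

test_that("the preprocessing chain preserves pixel count at every stage", {
  axis <- tiny_axis(150, 250, 1750)
  sp <- tiny_spectra(2, axis)
  sc <- make_scene(sp, axis, width = 8, height = 8, seed = 4,
                   baseline = baseline_spec(0.6), noise_sigma = 0.01,
                   n_spikes = 5)
  cfg <- preprocess_config(baseline = baseline_params(2, 1e4, 1e-4),
                           n_denoise_pcs = 3,
                           keep_ranges = list(c(500, 1500)),
                           excitation = 532)
  pp <- preprocess_image(sc$image, cfg)
  expect_equal(nrow(pp$derivative$cube), 64)
  expect_equal(nrow(pp$zero_order$cube), 64)
  expect_lt(ncol(pp$derivative$cube), length(axis))  # only trimming cuts channels
  expect_equal(pp$derivative$axis, pp$zero_order$axis)
  expect_equal(length(pp$baseline_labels), 64)
})

test_that("baseline correction reduces the residual background 10-fold", {
  axis <- tiny_axis(200, 250, 1750)
  sp <- tiny_spectra(2, axis)
  sc <- make_scene(sp, axis, width = 10, height = 10, seed = 5,
                   baseline = baseline_spec(1.0), noise_sigma = 0.005)
  bc <- baseline_correct_adaptive(sc$image, baseline_params(), seed = 1)
  res <- bc$baselines - sc$scene$baseline_field
  reduction <- median(abs(sc$scene$baseline_field)) / median(abs(res))
  expect_gte(reduction, 10)
})
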