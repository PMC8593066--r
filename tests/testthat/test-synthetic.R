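test_that("noiseless scene equals the bilinear product exactly", {
  sc <- tiny_scene(k = 3, noise_sigma = 0, n_spikes = 0)
  expect_identical(sc$image$cube,
                   sc$scene$true_maps %*% sc$scene$true_spectra)
  expect_true(all(sc$scene$true_maps >= 0))
  expect_equal(rowSums(sc$scene$true_spectra^2), rep(1, 3), tolerance = 1e-12)
})

test_that("scenes are bit-identical under the same seed", {
  a <- tiny_scene(noise_sigma = 0.05, n_spikes = 20, seed = 7,
                  baseline = baseline_spec(0.5))
  b <- tiny_scene(noise_sigma = 0.05, n_spikes = 20, seed = 7,
                  baseline = baseline_spec(0.5))
  expect_identical(a$image$cube, b$image$cube)
  expect_identical(a$scene$spikes, b$scene$spikes)
  c <- tiny_scene(noise_sigma = 0.05, n_spikes = 20, seed = 8,
                  baseline = baseline_spec(0.5))
  expect_false(identical(a$image$cube, c$image$cube))
})

test_that("spikes are single-channel impulses at recorded positions", {
  with_spikes <- tiny_scene(noise_sigma = 0.02, n_spikes = 100, seed = 5,
                            spike_amplitude = 10)
  twin <- tiny_scene(noise_sigma = 0.02, n_spikes = 0, seed = 5,
                     spike_amplitude = 10)
  delta <- with_spikes$image$cube - twin$image$cube
  hits <- which(delta != 0, arr.ind = TRUE)
  expect_equal(nrow(hits), 100)
  sp <- with_spikes$scene$spikes
  expect_setequal(paste(hits[, 1], hits[, 2]), paste(sp$pixel, sp$channel))
  expect_equal(delta[cbind(sp$pixel, sp$channel)], sp$amplitude)
  expect_true(all(sp$amplitude >= 10 * 0.02))
})

test_that("multiset scenes share the axis and honor absence flags exactly", {
  axis <- tiny_axis()
  sp <- tiny_spectra(3, axis)
  ms <- make_multiset_scene(sp, axis, n_images = 2, width = 10, height = 10,
                            absent = list(c(2L, 3L)), seed = 1,
                            noise_sigma = 0.01)
  expect_equal(ms$images[[1]]$axis, ms$images[[2]]$axis)
  expect_equal(ms$presence, matrix(c(1L, 1L, 1L, 1L, 1L, 0L), 2, 3))
  rows2 <- 101:200
  expect_true(all(ms$true_C[rows2, 3] == 0))
  expect_gt(sum(ms$true_C[1:100, 3]), 0)
})

test_that("all-present absence matrix gives every image the same model", {
  axis <- tiny_axis()
  sp <- tiny_spectra(2, axis)
  ms <- make_multiset_scene(sp, axis, n_images = 3, width = 9, height = 9,
                            absent = matrix(1L, 3, 2), seed = 3,
                            noise_sigma = 0)
  expect_true(all(ms$presence == 1L))
  expect_equal(nrow(ms$true_C), 3 * 81)
  for (im in ms$images) {
    expect_equal(dim(im$cube), c(81L, length(axis)))
  }
})

test_that("stacked ground-truth C covers every pixel of every image", {
  axis <- tiny_axis()
  sp <- tiny_spectra(3, axis)
  ms <- make_multiset_scene(sp, axis, n_images = 3, width = 8,
                            height = c(8, 10, 12), seed = 2, noise_sigma = 0)
  expect_equal(nrow(ms$true_C), 8 * 8 + 8 * 10 + 8 * 12)
})

test_that("degenerate layouts and absence sets are rejected", {
  expect_error(scene_layout(4, 4, 2), "8 x 8")
  expect_error(scene_layout(12, 12, 2, absent = 1:2), "all components")
  axis <- tiny_axis()
  sp <- tiny_spectra(2, axis)
  expect_error(
    make_multiset_scene(sp, axis, n_images = 2,
                        absent = list(c(1L, 1L), c(1L, 2L)), seed = 1),
    "at least one component")
})

test_that("heteroscedastic noise scales with the local signal", {
  sc_hom <- tiny_scene(noise_sigma = 0.05, seed = 9)
  sc_het <- tiny_scene(noise_sigma = 0.05, seed = 9, heteroscedastic = TRUE)
  clean <- sc_hom$scene$true_maps %*% sc_hom$scene$true_spectra
  res_het <- sc_het$image$cube - clean
  hi <- clean > quantile(clean, 0.99)
  lo <- clean < quantile(clean, 0.5)
  expect_gt(sd(res_het[hi]), sd(res_het[lo]))
})
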