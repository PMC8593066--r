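test_that("zero-order recovery inverts exact bilinear data", {
  axis <- tiny_axis(100)
  S0 <- tiny_spectra(3, axis)
  set.seed(1)
  C <- matrix(stats::rgamma(200 * 3, 2), 200, 3)
  D0 <- C %*% S0
  rec <- recover_zero_order(C, D0)
  expect_equal(rec, S0, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("recovery equals the normal-equations oracle on noisy data", {
  axis <- tiny_axis(100)
  S0 <- tiny_spectra(3, axis)
  set.seed(2)
  C <- matrix(stats::rgamma(150 * 3, 2), 150, 3)
  D0 <- C %*% S0 + matrix(rnorm(150 * 100, sd = 0.01), 150)
  rec <- recover_zero_order(C, D0)
  oracle <- solve(t(C) %*% C, t(C) %*% D0)
  oracle <- oracle / sqrt(rowSums(oracle^2))
  expect_equal(rec, oracle, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(recover_zero_order(C[1:10, ], D0), "rows")
  C_bad <- cbind(C[, 1], C[, 1] * (1 + 1e-13), C[, 2])
  expect_warning(recover_zero_order(C_bad, D0), "ridge|ill-conditioned")
})

test_that("recovered synthetic components peak at their marker bands", {
  axis <- default_axis(785)
  subs <- c("Lignin", "Arabinogalactan", "Crystalline waxes")
  sp <- do.call(rbind, lapply(subs, make_component_spectrum,
                              axis = axis, excitation = 785))
  sc <- make_scene(sp, axis, width = 16, height = 16, seed = 3,
                   noise_sigma = 0.002)
  fitC <- mcr_update_c(sc$image$cube, sp)     # true spectra, solve maps
  rec <- recover_zero_order(fitC, sc$image$cube)
  step <- diff(axis)[1]
  tbl <- marker_band_table(785)
  for (j in seq_along(subs)) {
    pk <- find_peaks(rec[j, ], axis, prominence = 0.01)
    bands <- tbl$position[tbl$substance == subs[j]]
    for (b in bands) {
      expect_lte(min(abs(pk$position - b)), 2 * step,
                 label = sprintf("%s band %.0f recovered", subs[j], b))
    }
  }
})

test_that("component/reference PCA places components next to their generators", {
  axis <- tiny_axis(150)
  refs <- tiny_spectra(4, axis)
  set.seed(4)
  comps <- refs + matrix(rnorm(length(refs), sd = 0.002), nrow(refs))
  res <- pca_components_refs(comps, refs,
                             component_labels = paste0("C", 1:4),
                             ref_labels = paste0("R", 1:4))
  expect_equal(res$kind, rep(c("component", "reference"), each = 4))
  expect_true(all(diff(res$explained) <= 1e-9))
  d3 <- as.matrix(dist(res$scores[, 1:3]))
  for (j in 1:4) {
    nn <- which.min(d3[j, 5:8])
    expect_equal(unname(nn), j)          # nearest reference is the generator
  }
})

test_that("PCA scores are invariant to sample order and duplicates coincide", {
  axis <- tiny_axis(120)
  refs <- tiny_spectra(3, axis)
  set.seed(5)
  comps <- refs[c(1, 1, 2, 3), ] + matrix(rnorm(4 * 120, sd = 0.001), 4)
  comps[2, ] <- comps[1, ]               # exact duplicate
  res <- pca_components_refs(comps, refs)
  expect_equal(res$scores[1, ], res$scores[2, ], tolerance = 1e-10)

  perm <- c(3, 1, 4, 2)
  res_p <- pca_components_refs(comps[perm, ], refs,
                               component_labels = paste0("C", perm))
  npc <- min(ncol(res_p$scores), ncol(res$scores))
  expect_equal(res_p$scores[order(perm), seq_len(npc)],
               res$scores[1:4, seq_len(npc)], tolerance = 1e-8)
  expect_equal(res_p$scores[5:7, seq_len(npc)],
               res$scores[5:7, seq_len(npc)], tolerance = 1e-8)
})

test_that("PCA exclusions and validation behave as documented", {
  axis <- tiny_axis(100)
  refs <- tiny_spectra(3, axis)
  res <- pca_components_refs(refs, refs, component_labels = c("a", "b", "c"),
                             ref_labels = c("d", "e", "f"),
                             exclusions = c("a", "d"))
  expect_equal(length(res$labels), 4)
  expect_false(any(res$labels %in% c("a", "d")))
  expect_equal(res$cv$splits, 10)
  expect_equal(res$cv$thickness, 2)
  expect_error(pca_components_refs(refs[, 1:50], refs), "axis")
  expect_error(pca_components_refs(refs[1, , drop = FALSE],
                                   refs[1, , drop = FALSE]), "3 samples")
})

test_that("marker-band matching identifies lignin and ranks flavonoids over it", {
  axis <- default_axis(532)
  y <- make_component_spectrum("Lignin", axis, 532)
  r <- match_bands(y, axis, 532)
  expect_equal(r$substance[1], "Lignin")

  axis785 <- default_axis(785)
  yf <- make_component_spectrum("Flavonoids", axis785, 785)
  rf <- match_bands(yf, axis785, 785)
  expect_equal(rf$substance[1], "Flavonoids")
  expect_gt(rf$score[rf$substance == "Flavonoids"],
            rf$score[rf$substance == "Lignin"])
})

test_that("matching is scale-invariant and a flat spectrum yields no ranking", {
  axis <- default_axis(785)
  y <- make_component_spectrum("Arabinogalactan", axis, 785)
  r1 <- match_bands(y, axis, 785)
  r2 <- match_bands(1e4 * y, axis, 785)
  expect_equal(r1$score, r2$score)
  expect_equal(r1$substance, r2$substance)
  flat <- match_bands(rep(1, length(axis)), axis, 785)
  expect_equal(nrow(flat), 0)
})

test_that("peak detection honors prominence and separation", {
  x <- seq(0, 100, length.out = 201)
  y <- exp(-((x - 30) / 3)^2) + 0.5 * exp(-((x - 60) / 3)^2) +
    0.02 * exp(-((x - 90) / 2)^2)
  pk <- find_peaks(y, x, prominence = 0.05)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$position, c(30, 60), tolerance = 0.5)
  pk_all <- find_peaks(y, x, prominence = 0.01)
  expect_equal(nrow(pk_all), 3)
})
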