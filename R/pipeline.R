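#' Default pipeline configuration
#'
#' Returns the full declarative configuration of an end-to-end run as a named
#' list, optionally starting from one of two presets that mirror the two
#' acquisition setups:
#' * `"spruce-like"`: 532 nm excitation, axis 250-3740 cm^-1 at 3.8 cm^-1,
#'   image-norm multiset scaling on, 15 denoising PCs.
#' * `"larch-like"`: 785 nm excitation, axis 250-1750 cm^-1 at 2.7 cm^-1,
#'   no image-norm scaling, 10 denoising PCs, correspondence constraint
#'   available via `simulate$absent`.
#'
#' @param preset `"spruce-like"` or `"larch-like"`.
#' @return Nested named list with sections `seed`, `simulate`, `preprocess`,
#'   `multiset`, `decompose`, `identify`.
#' @export
default_config <- function(preset = c("spruce-like", "larch-like")) {
  preset <- match.arg(preset)
  ex <- if (preset == "spruce-like") 532 else 785
  substances <- if (preset == "spruce-like") {
    c("Lignin", "Cellulose perpendicular", "Lignans")
  } else {
    c("Lignin", "Cellulose perpendicular", "Flavonoids")
  }
  list(
    seed = 1L,
    simulate = list(
      excitation = ex,
      substances = substances,
      n_images = 2L,
      width = 32L, height = 32L,
      pixel_spacing = if (ex == 532) 333 else 400,
      snr = 20,
      baseline_amplitude = 1.0,
      n_spikes = 50L,
      absent = list()
    ),
    preprocess = list(
      median_window = 3L,
      n_clusters = 4L,
      lambda = if (ex == 532) 1e5 else 1e4,
      p = 1e-4,
      n_denoise_pcs = if (ex == 532) 15L else 10L,
      sg_window = 11L,
      sg_polyorder = 2L
    ),
    multiset = list(
      normalize_by_image_norm = (ex == 532)
    ),
    decompose = list(
      n_components = NULL,
      drop_threshold = 0.05,
      noise_alpha = 0.10,
      tol = 1e-3,
      max_iter = 50L
    ),
    identify = list(
      tolerance_cm1 = 8,
      prominence = 0.05
    )
  )
}

config_keys <- list(
  top = c("seed", "simulate", "preprocess", "multiset", "decompose",
          "identify", "preset"),
  simulate = c("excitation", "substances", "n_images", "width", "height",
               "pixel_spacing", "snr", "baseline_amplitude", "n_spikes",
               "absent"),
  preprocess = c("median_window", "n_clusters", "lambda", "p",
                 "n_denoise_pcs", "sg_window", "sg_polyorder"),
  multiset = "normalize_by_image_norm",
  decompose = c("n_components", "drop_threshold", "noise_alpha", "tol",
                "max_iter"),
  identify = c("tolerance_cm1", "prominence")
)

#' Read and validate a pipeline configuration
#'
#' Reads a YAML run configuration, merges it over the preset defaults and
#' rejects unknown keys (catching typos before a long run).
#'
#' @param path YAML file path, or a named list already in memory.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) stop("configuration must be a mapping")
  base <- default_config(cfg$preset %||% "spruce-like")
  unknown <- setdiff(names(cfg), config_keys$top)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  for (sec in intersect(names(cfg), names(config_keys)[-1])) {
    bad <- setdiff(names(cfg[[sec]]), config_keys[[sec]])
    if (length(bad)) {
      stop("unknown key(s) in '", sec, "': ", paste(bad, collapse = ", "))
    }
  }
  cfg$preset <- NULL
  # two-level merge with wholesale replacement of leaf values (modifyList
  # would merge unnamed lists like `absent` by name and lose them)
  out <- base
  for (sec in names(cfg)) {
    if (is.list(base[[sec]]) && is.list(cfg[[sec]])) {
      for (kk in names(cfg[[sec]])) out[[sec]][[kk]] <- cfg[[sec]][[kk]]
    } else {
      out[[sec]] <- cfg[[sec]]
    }
  }
  if (!out$simulate$excitation %in% c(532, 785)) {
    stop("simulate$excitation must be 532 or 785")
  }
  out
}

provenance_write <- function(dir, stage, params) {
  path <- file.path(dir, "provenance.json")
  log <- if (file.exists(path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    list(package = "ramanmcr",
         version = as.character(utils::packageVersion("ramanmcr")),
         r_version = R.version.string, stages = list())
  }
  log$stages[[stage]] <- params
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

state_path <- function(dir) file.path(dir, "state.rds")

load_state <- function(dir) {
  p <- state_path(dir)
  if (!file.exists(p)) stop("no pipeline state in ", dir,
                            "; run earlier stages first")
  readRDS(p)
}

save_state <- function(dir, state) {
  saveRDS(state, state_path(dir))
  invisible(state)
}

#' Pipeline stage: simulate a multi-image scene
#'
#' Generates the study images from marker-band-derived component spectra
#' with region-dependent fluorescence baselines, Gaussian noise at the
#' configured SNR and cosmic-ray spikes, and writes the cubes plus ground
#' truth (spectra CSV, per-image map CSVs, scene JSON) to `dir`.
#'
#' @param config A configuration list (see [read_config()]).
#' @param dir Output/run directory.
#' @param seed Optional seed overriding `config$seed`.
#' @return The pipeline state, invisibly.
#' @export
pipeline_simulate <- function(config, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- config$simulate
  seed <- as.integer(seed %||% config$seed)
  axis <- default_axis(sc$excitation)
  spectra <- do.call(rbind, lapply(sc$substances, function(s) {
    make_component_spectrum(s, axis, excitation = sc$excitation)
  }))
  absent <- lapply(sc$absent, function(p) as.integer(unlist(p)))
  sigma <- if (sc$snr > 0) {
    lay <- scene_layout(sc$width, sc$height, nrow(spectra), seed = seed)
    noise_sigma_for_snr(lay$maps, spectra, sc$snr)
  } else 0
  ms <- make_multiset_scene(
    spectra, axis, n_images = sc$n_images, absent = absent,
    width = sc$width, height = sc$height, seed = seed,
    baseline = baseline_spec(sc$baseline_amplitude),
    noise_sigma = sigma, n_spikes = sc$n_spikes,
    excitation = sc$excitation, pixel_spacing = sc$pixel_spacing
  )
  for (i in seq_along(ms$images)) {
    write_cube(ms$images[[i]], file.path(dir, sprintf("image%02d.csv", i)))
  }
  write_spectra_csv(ms$spectra, axis, file.path(dir, "truth_spectra.csv"),
                    names = sc$substances)
  jsonlite::write_json(
    list(substances = sc$substances, presence = ms$presence,
         noise_sigma = sigma, seed = seed),
    file.path(dir, "truth_scene.json"), auto_unbox = TRUE, digits = NA
  )
  provenance_write(dir, "simulate",
                   c(sc, list(seed = seed, noise_sigma = sigma)))
  state <- list(config = config, seed = seed, images = ms$images,
                truth = ms)
  save_state(dir, state)
  invisible(state)
}

#' Pipeline stage: preprocess all images
#'
#' @param config Configuration list.
#' @param dir Run directory holding the simulate (or imported) state.
#' @return The updated state, invisibly.
#' @export
pipeline_preprocess <- function(config, dir) {
  state <- load_state(dir)
  pc <- config$preprocess
  pconf <- preprocess_config(
    median_window = pc$median_window,
    baseline = baseline_params(pc$n_clusters, pc$lambda, pc$p),
    n_denoise_pcs = pc$n_denoise_pcs,
    sg_window = pc$sg_window, sg_polyorder = pc$sg_polyorder,
    excitation = config$simulate$excitation,
    seed = state$seed
  )
  state$preprocessed <- lapply(state$images, preprocess_image, config = pconf)
  provenance_write(dir, "preprocess", unclass(pconf)[
    setdiff(names(unclass(pconf)), "baseline")])
  save_state(dir, state)
  invisible(state)
}

#' Pipeline stage: multiset assembly and MCR-ALS decomposition
#'
#' Builds derivative and zero-order multisets, estimates the component count
#' from the singular value trace (unless overridden), selects purest-pixel
#' initial estimates on the zero-order data, derivatizes them with the same
#' filter, and runs constrained MCR-ALS on the derivative multiset.
#'
#' @param config Configuration list.
#' @param dir Run directory.
#' @param n_components Optional expert override of the component count.
#' @return The updated state, invisibly.
#' @export
pipeline_decompose <- function(config, dir, n_components = NULL) {
  state <- load_state(dir)
  if (is.null(state$preprocessed)) stop("run the preprocess stage first")
  dc <- config$decompose
  norm_flag <- isTRUE(config$multiset$normalize_by_image_norm)
  m_deriv <- augment(lapply(state$preprocessed, `[[`, "derivative"),
                     normalize_by_image_norm = norm_flag)
  m_zero <- augment(lapply(state$preprocessed, `[[`, "zero_order"),
                    normalize_by_image_norm = norm_flag)
  m_rank <- augment(lapply(state$preprocessed, `[[`, "zero_order_predenoise"),
                    normalize_by_image_norm = norm_flag)
  rank <- estimate_rank(m_rank, drop_threshold = dc$drop_threshold)
  k <- as.integer(n_components %||% dc$n_components %||% rank$chosen_k)
  if (!is.null(n_components %||% dc$n_components)) {
    rank$user_override <- k
  }
  init <- simplisma(m_zero, k, noise_alpha = dc$noise_alpha)
  S0 <- derivative_sg(init$spectra, config$preprocess$sg_window,
                      config$preprocess$sg_polyorder)
  corr <- NULL
  absent <- config$simulate$absent
  if (length(absent)) {
    corr <- build_correspondence(length(state$images), k,
                                 lapply(absent, function(p) as.integer(unlist(p))))
  }
  model <- mcr_als(m_deriv, S0, corr = corr, tol = dc$tol,
                   max_iter = dc$max_iter)
  state$multiset_deriv <- m_deriv
  state$multiset_zero <- m_zero
  state$rank <- rank
  state$init <- init
  state$model <- model
  jsonlite::write_json(
    c(as.list(glance.component_model(model)),
      list(chosen_k = rank$chosen_k, override = rank$user_override,
           singular_values = head(rank$singular_values, 15))),
    file.path(dir, "model_stats.json"), auto_unbox = TRUE, digits = NA
  )
  write_component_maps(model, file.path(dir, "maps"))
  provenance_write(dir, "decompose",
                   list(k = k, chosen_k = rank$chosen_k,
                        user_override = rank$user_override,
                        drop_threshold = dc$drop_threshold,
                        noise_alpha = dc$noise_alpha, tol = dc$tol,
                        max_iter = dc$max_iter,
                        normalize_by_image_norm = norm_flag,
                        lof_percent = model$lof_percent,
                        r2_percent = model$r2_percent,
                        n_iter = model$n_iter))
  save_state(dir, state)
  invisible(state)
}

#' Pipeline stage: recover zero-order component spectra
#'
#' @param config Configuration list.
#' @param dir Run directory.
#' @return The updated state, invisibly.
#' @export
pipeline_recover <- function(config, dir) {
  state <- load_state(dir)
  if (is.null(state$model)) stop("run the decompose stage first")
  rec <- recover_zero_order(state$model$C, state$multiset_zero)
  state$recovered <- rec
  write_spectra_csv(rec, state$multiset_zero$axis,
                    file.path(dir, "recovered_spectra.csv"))
  provenance_write(dir, "recover", list(k = nrow(rec)))
  save_state(dir, state)
  invisible(state)
}

#' Pipeline stage: identify components from marker bands
#'
#' @param config Configuration list.
#' @param dir Run directory.
#' @return The updated state, invisibly.
#' @export
pipeline_identify <- function(config, dir) {
  state <- load_state(dir)
  if (is.null(state$recovered)) stop("run the recover stage first")
  idc <- config$identify
  ex <- config$simulate$excitation
  axis <- state$multiset_zero$axis
  rankings <- lapply(seq_len(nrow(state$recovered)), function(j) {
    match_bands(state$recovered[j, ], axis, excitation = ex,
                tolerance_cm1 = idc$tolerance_cm1,
                prominence = idc$prominence)
  })
  state$identification <- rankings
  report <- lapply(seq_along(rankings), function(j) {
    r <- rankings[[j]]
    if (!nrow(r)) return(list(component = j, top = NULL))
    list(component = j, top = r$substance[1], score = r$score[1],
         runner_up = if (nrow(r) > 1) r$substance[2] else NULL)
  })
  jsonlite::write_json(report, file.path(dir, "identification.json"),
                       auto_unbox = TRUE, digits = NA)
  txt <- vapply(report, function(x) {
    sprintf("C%-2d -> %-28s (score %.2f)", x$component,
            x$top %||% "(no peaks)", x$score %||% NA_real_)
  }, character(1))
  writeLines(txt, file.path(dir, "identification.txt"))
  provenance_write(dir, "identify", idc)
  save_state(dir, state)
  invisible(state)
}

#' Run the full pipeline end-to-end
#'
#' Executes simulate, preprocess, decompose, recover and identify in order,
#' writing all artifacts and a provenance log into `dir`. Given the same
#' configuration and seed, deterministic stages reproduce their outputs
#' bit-for-bit.
#'
#' @param config Configuration list or YAML path.
#' @param dir Run directory.
#' @param seed Optional seed override.
#' @param n_components Optional expert override of the component count.
#' @return The final state, invisibly.
#' @export
run_pipeline <- function(config, dir, seed = NULL, n_components = NULL) {
  config <- read_config(config)
  pipeline_simulate(config, dir, seed = seed)
  pipeline_preprocess(config, dir)
  pipeline_decompose(config, dir, n_components = n_components)
  pipeline_recover(config, dir)
  state <- pipeline_identify(config, dir)
  invisible(state)
}

#' Summarize a finished pipeline run
#'
#' @param dir Run directory.
#' @return Character vector of report lines (also printed).
#' @export
pipeline_report <- function(dir) {
  state <- load_state(dir)
  lines <- character(0)
  if (!is.null(state$model)) {
    g <- glance.component_model(state$model)
    lines <- c(lines, sprintf(
      "model: k = %d, LOF = %.4g %%, R2 = %.4f %%, %d iterations (%s)",
      g$k, g$lof_percent, g$r2_percent, g$n_iter,
      if (g$converged) "converged" else "not converged"))
  }
  if (!is.null(state$rank)) {
    lines <- c(lines, sprintf("rank estimate: chosen_k = %d%s",
                              state$rank$chosen_k,
                              if (!is.na(state$rank$user_override))
                                sprintf(" (override %d)", state$rank$user_override)
                              else ""))
  }
  idpath <- file.path(dir, "identification.txt")
  if (file.exists(idpath)) lines <- c(lines, readLines(idpath))
  cat(lines, sep = "\n")
  invisible(lines)
}
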