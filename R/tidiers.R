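#' Tidy a fitted component model
#'
#' @param x A `component_model`.
#' @param ... Unused.
#' @return Tibble with one row per (component, channel): `component`,
#'   `wavenumber` (channel index when the model has no axis), `intensity`.
#' @method tidy component_model
#' @export
tidy.component_model <- function(x, ...) {
  k <- x$k
  nc <- ncol(x$S_T)
  wn <- x$axis %||% seq_len(nc)
  tibble::tibble(
    component = rep(paste0("C", seq_len(k)), each = nc),
    wavenumber = rep(wn, k),
    intensity = as.vector(t(x$S_T))
  )
}

#' One-row summary of a fitted component model
#'
#' @param x A `component_model`.
#' @param ... Unused.
#' @return Tibble with `k`, `lof_percent`, `r2_percent`, `n_iter`,
#'   `converged`.
#' @method glance component_model
#' @export
glance.component_model <- function(x, ...) {
  tibble::tibble(k = x$k, lof_percent = x$lof_percent,
                 r2_percent = x$r2_percent, n_iter = x$n_iter,
                 converged = x$converged)
}

#' Tidy a rank estimate
#'
#' @param x A `rank_estimate`.
#' @param ... Unused.
#' @return Tibble with `k`, `singular_value`, `relative_drop`, `chosen`.
#' @method tidy rank_estimate
#' @export
tidy.rank_estimate <- function(x, ...) {
  n <- length(x$singular_values)
  tibble::tibble(
    k = seq_len(n),
    singular_value = x$singular_values,
    relative_drop = c(x$criterion_trace,
                      rep(NA_real_, n - length(x$criterion_trace))),
    chosen = seq_len(n) == x$chosen_k
  )
}

#' Tidy a PCA of components and references
#'
#' @param x A `pca_result`.
#' @param ... Unused.
#' @return Tibble with `label`, `kind` and one column per PC score.
#' @method tidy pca_result
#' @export
tidy.pca_result <- function(x, ...) {
  out <- tibble::tibble(label = x$labels, kind = x$kind)
  for (j in seq_len(ncol(x$scores))) out[[paste0("PC", j)]] <- x$scores[, j]
  out
}

#' @method glance pca_result
#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(n_pcs = ncol(x$scores),
                 explained_total = sum(x$explained),
                 best_cv_k = if (all(is.na(x$cv_error))) NA_integer_
                             else which.min(x$cv_error))
}

#' Plot resolved component spectra
#'
#' @param object A `component_model`.
#' @param ... Unused.
#' @return A ggplot object (one facet per component).
#' @method autoplot component_model
#' @export
autoplot.component_model <- function(object, ...) {
  df <- tidy.component_model(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavenumber, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "Raman shift (cm^-1)", y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Scree plot of a rank estimate
#'
#' @param object A `rank_estimate`.
#' @param n_show Number of singular values plotted.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rank_estimate
#' @export
autoplot.rank_estimate <- function(object, n_show = 20, ...) {
  df <- tidy.rank_estimate(object)
  df <- df[seq_len(min(n_show, nrow(df))), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$singular_value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "component", y = "singular value") +
    ggplot2::theme_minimal()
}

#' Score plot of a component/reference PCA
#'
#' @param object A `pca_result`.
#' @param pcs Two PC indices to plot (default first two).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pca_result
#' @export
autoplot.pca_result <- function(object, pcs = c(1, 2), ...) {
  df <- tidy.pca_result(object)
  xs <- paste0("PC", pcs[1]); ys <- paste0("PC", pcs[2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xs]], y = .data[[ys]],
                                   colour = .data$kind)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", xs, object$explained[pcs[1]]),
      y = sprintf("%s (%.1f%%)", ys, object$explained[pcs[2]])
    ) +
    ggplot2::theme_minimal()
}
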