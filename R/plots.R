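# ggplot2 graphics for spectra, identifications and evaluations.

#' Plot raw or preprocessed spectra
#'
#' Line plot of intensity against m/z, one facet per sample, replicates
#' coloured.
#'
#' @param spectra A spectra tibble.
#' @param samples Optional subset of sample ids to show.
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra, samples = NULL) {
  check_spectra(spectra)
  if (!is.null(samples)) {
    spectra <- spectra |> dplyr::filter(.data$sample_id %in% samples)
  }
  ggplot2::ggplot(spectra,
                  ggplot2::aes(x = .data$mz, y = .data$intensity,
                               colour = factor(.data$replicate))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample_id), scales = "free_y") +
    ggplot2::labs(x = "m/z (Da)", y = "intensity", colour = "replicate") +
    ggplot2::theme_minimal()
}

#' Plot an identification: sample peaks with best-candidate windows
#'
#' Stem plot of the sample's peaks overlaid with the match windows of the
#' top-ranked candidate's reference markers.
#'
#' @param object A `zooms_id` object.
#' @param peaks The peaks tibble the identification was run on.
#' @param sample Sample id to plot; defaults to the first.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot zooms_id
#' @export
autoplot.zooms_id <- function(object, peaks = NULL, sample = NULL, ...) {
  res <- object$results
  sample <- sample %||% res$sample_id[1]
  best <- res |>
    dplyr::filter(.data$sample_id == sample, .data$rank == 1) |>
    dplyr::slice(1)
  if (!nrow(best)) {
    stop("no candidates for sample '", sample, "'", call. = FALSE)
  }
  mm <- best$matched_markers[[1]]
  window <- object$cfg$window
  p <- ggplot2::ggplot()
  if (!is.null(mm) && nrow(mm)) {
    p <- p + ggplot2::geom_rect(
      data = mm,
      ggplot2::aes(xmin = .data$ref_mass + window[1],
                   xmax = .data$ref_mass + window[2],
                   ymin = -Inf, ymax = Inf),
      fill = "steelblue", alpha = 0.25
    )
  }
  if (!is.null(peaks)) {
    pk <- peaks |> dplyr::filter(.data$sample_id == sample)
    p <- p + ggplot2::geom_segment(
      data = pk,
      ggplot2::aes(x = .data$mz, xend = .data$mz, y = 0,
                   yend = .data$intensity),
      linewidth = 0.4
    )
  }
  p +
    ggplot2::labs(
      title = sprintf("%s: %s (r = %.3f, %s)", sample, best$species,
                      best$correlation, best$status),
      x = "m/z (Da)", y = "intensity"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-site accuracies of an evaluation
#'
#' @param object A `zooms_eval` object.
#' @param ... Unused.
#' @return A ggplot bar chart of accuracy per site and taxonomic level.
#' @method autoplot zooms_eval
#' @export
autoplot.zooms_eval <- function(object, ...) {
  ggplot2::ggplot(object$per_site,
                  ggplot2::aes(x = .data$site, y = .data$accuracy,
                               fill = .data$level)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "accuracy (%)", fill = "level") +
    ggplot2::theme_minimal()
}

#' Confusion-map heatmap
#'
#' Row-normalized heatmap of manual (rows) against predicted (columns)
#' labels.
#'
#' @param object A `zooms_confusion` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot zooms_confusion
#' @export
autoplot.zooms_confusion <- function(object, ...) {
  d <- tidy.zooms_confusion(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                  fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "predicted", y = "manual", fill = "proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
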