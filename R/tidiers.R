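# broom-style tidiers for fitted/result objects.

#' Tidy identification results
#'
#' @param x A `zooms_id` object.
#' @param ... Unused.
#' @return The candidate table: one row per sample and candidate with
#'   species, lineage, correlation, rank, matched-marker count and status.
#' @method tidy zooms_id
#' @export
tidy.zooms_id <- function(x, ...) {
  x$results |>
    dplyr::mutate(
      n_matched_markers = as.integer(.data$n_matched_markers)
    ) |>
    dplyr::select(-"matched_markers")
}

#' One-row summary of an identification batch
#'
#' @param x A `zooms_id` object.
#' @param ... Unused.
#' @return A one-row tibble: sample counts by status, mean top correlation,
#'   number of contaminant hits.
#' @method glance zooms_id
#' @export
glance.zooms_id <- function(x, ...) {
  per_sample <- x$results |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(status = dplyr::first(.data$status),
                     top_correlation = dplyr::first(.data$correlation),
                     .groups = "drop")
  tibble(
    n_samples = nrow(per_sample),
    n_ok = sum(per_sample$status == "ok"),
    n_tentative = sum(per_sample$status == "tentative"),
    n_fail = sum(per_sample$status == "fail"),
    mean_top_correlation = mean(per_sample$top_correlation, na.rm = TRUE),
    n_contaminant_hits = nrow(x$contaminant_hits)
  )
}

#' Tidy an evaluation report
#'
#' @param x A `zooms_eval` object.
#' @param ... Unused.
#' @return Per-site accuracies, long over taxonomic levels.
#' @method tidy zooms_eval
#' @export
tidy.zooms_eval <- function(x, ...) {
  x$per_site
}

#' One-row summary of an evaluation report
#'
#' @param x A `zooms_eval` object.
#' @param ... Unused.
#' @return A one-row tibble with the weighted accuracy per level, the
#'   number of evaluated pairs and excluded fails, and the true-vs-false
#'   score t-test (when computable).
#' @method glance zooms_eval
#' @export
glance.zooms_eval <- function(x, ...) {
  wide <- x$weighted |>
    dplyr::select("level", "accuracy") |>
    tidyr::pivot_wider(names_from = "level", values_from = "accuracy",
                       names_prefix = "accuracy_")
  out <- dplyr::bind_cols(
    tibble(n = sum(x$weighted$n[x$weighted$level == "taxon"]),
           n_excluded_fails = x$n_excluded_fails),
    wide
  )
  if (!is.null(x$ttest)) {
    out$t_scores <- x$ttest$t
    out$p_scores <- x$ttest$p_value
  }
  out
}

#' Tidy a confusion matrix
#'
#' @param x A `zooms_confusion` object.
#' @param ... Unused.
#' @return A tibble `truth`, `predicted`, `n`, `proportion` (row-wise).
#' @method tidy zooms_confusion
#' @export
tidy.zooms_confusion <- function(x, ...) {
  m <- x$counts
  rs <- rowSums(m)
  as_tibble(as.data.frame.table(m, responseName = "n")) |>
    dplyr::rename(truth = "truth", predicted = "predicted") |>
    dplyr::mutate(
      truth = as.character(.data$truth),
      predicted = as.character(.data$predicted),
      n = as.integer(.data$n),
      proportion = .data$n / pmax(rs[.data$truth], 1)
    )
}
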