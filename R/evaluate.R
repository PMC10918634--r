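# Comparison of algorithmic identifications with manual labels:
# compound-label matching, confusion matrices, per-site and sample-size
# weighted accuracies, and t-tests on correlation scores.

fail_tokens <- c("", "fail", "failed", "unknown", "na", "n/a", "none")

#' Is a label a fail marker?
#'
#' @param x Character vector of labels.
#' @return Logical vector: `TRUE` for missing/empty labels or fail words.
#' @export
is_fail_label <- function(x) {
  is.na(x) | tolower(stringr::str_squish(as.character(x))) %in% fail_tokens
}

#' Split a (possibly compound) taxon label into atoms
#'
#' ZooMS taxa are often compound ("Cervus/Saiga/Gazella sp."). Labels are
#' case-folded, `sp.`/`sp` suffixes, question marks and stray punctuation
#' are stripped, and the label is split on `/` into a set of atomic taxon
#' tokens.
#'
#' @param x Character vector of labels.
#' @return A list of character vectors (one set of atoms per label).
#' @export
label_atoms <- function(x) {
  x <- tolower(as.character(x))
  x <- stringr::str_replace_all(x, "[?]", "")
  purrr::map(stringr::str_split(x, "/"), function(parts) {
    parts <- stringr::str_remove_all(parts, "\\bsp(p)?\\.?$")
    parts <- stringr::str_remove_all(parts, "[.]")
    parts <- stringr::str_squish(parts)
    unique(parts[nzchar(parts)])
  })
}

#' Compound-label match
#'
#' Two labels match when their atom sets intersect: a prediction of
#' "Cervus/Saiga/Gazella/Rangifer sp." against a manual
#' "Cervus/Saiga/Gazella sp." is a match. The relation is symmetric.
#'
#' @param predicted,truth Character vectors of equal length (or length 1,
#'   recycled).
#' @return A logical vector.
#' @export
is_match <- function(predicted, truth) {
  n <- max(length(predicted), length(truth))
  predicted <- rep_len(predicted, n)
  truth <- rep_len(truth, n)
  a <- label_atoms(predicted)
  b <- label_atoms(truth)
  purrr::map2_lgl(a, b, function(x, y) length(intersect(x, y)) > 0)
}

#' Confusion matrix of predicted vs manual labels
#'
#' Counts label pairs over the union of observed labels. Fails must be
#' excluded beforehand (see [evaluate_identifications()]).
#'
#' @param predicted,truth Equal-length character vectors.
#' @param normalize Row-normalize the counts for display.
#' @return A `zooms_confusion` object wrapping the counts matrix (rows:
#'   truth, columns: predicted).
#' @export
confusion_matrix <- function(predicted, truth, normalize = FALSE) {
  if (!length(predicted) || length(predicted) != length(truth)) {
    stop("need equal-length, nonempty label vectors", call. = FALSE)
  }
  predicted <- stringr::str_squish(as.character(predicted))
  truth <- stringr::str_squish(as.character(truth))
  labels <- sort(unique(c(predicted, truth)))
  counts <- table(factor(truth, levels = labels),
                  factor(predicted, levels = labels))
  m <- matrix(as.integer(counts), nrow = length(labels),
              dimnames = list(truth = labels, predicted = labels))
  structure(list(counts = m, labels = labels, normalized = normalize),
            class = "zooms_confusion")
}

#' @export
print.zooms_confusion <- function(x, ...) {
  cat("<zooms_confusion>", nrow(x$counts), "labels,", sum(x$counts),
      "pairs\n")
  m <- x$counts
  if (isTRUE(x$normalized)) {
    rs <- rowSums(m)
    m <- sweep(m, 1, pmax(rs, 1), "/")
  }
  print(m)
  invisible(x)
}

#' Identification accuracy of a set of label pairs
#'
#' Percentage of pairs where the predicted and manual labels match under
#' the compound-label rule ([is_match()]).
#'
#' @param predicted,truth Equal-length character vectors (fails removed).
#' @return Accuracy in percent.
#' @export
site_accuracy <- function(predicted, truth) {
  if (!length(predicted) || length(predicted) != length(truth)) {
    stop("need equal-length, nonempty label vectors", call. = FALSE)
  }
  100 * mean(is_match(predicted, truth))
}

#' Sample-size weighted accuracy
#'
#' Combines per-site accuracies into one figure weighted by site sample
#' size: `sum(n * accuracy) / sum(n)`.
#'
#' @param n Integer vector of per-site sample sizes (all positive).
#' @param accuracy Numeric vector of per-site accuracies, percent.
#' @return The weighted accuracy in percent.
#' @export
weighted_accuracy <- function(n, accuracy) {
  if (!length(n) || length(n) != length(accuracy)) {
    stop("need equal-length, nonempty `n` and `accuracy`", call. = FALSE)
  }
  if (any(n <= 0)) {
    stop("all site sample sizes must be positive", call. = FALSE)
  }
  sum(n * accuracy) / sum(n)
}

#' t-test on true vs false identification correlation scores
#'
#' Two-sample t-test comparing the correlation scores of correctly and
#' incorrectly identified samples; Welch's unequal-variance form by
#' default.
#'
#' @param true_scores,false_scores Numeric score vectors, each of length at
#'   least 2.
#' @param var_equal Use the pooled-variance Student form instead of Welch.
#' @return A one-row tibble: `t`, `df`, `p_value`, group means, sds and
#'   sizes.
#' @export
ttest_scores <- function(true_scores, false_scores, var_equal = FALSE) {
  if (length(true_scores) < 2 || length(false_scores) < 2) {
    stop("each score group needs at least 2 values", call. = FALSE)
  }
  ht <- t.test(true_scores, false_scores, var.equal = var_equal)
  tibble(
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_true = mean(true_scores),
    mean_false = mean(false_scores),
    sd_true = stats::sd(true_scores),
    sd_false = stats::sd(false_scores),
    n_true = length(true_scores),
    n_false = length(false_scores)
  )
}

#' Evaluate identifications against manual labels
#'
#' Joins rank-1 algorithmic identifications to a manual-label table,
#' removes pairs where either side is a fail, and computes per-site and
#' weighted accuracies (taxon level; family and order too when the truth
#' table carries `manual_family` / `manual_order`), a taxon-level confusion
#' matrix, and a t-test comparing correlation scores of true and false
#' identifications. When rank 1 is tied, a sample counts as correct if any
#' tied candidate matches, and the confusion matrix uses the first tied
#' candidate.
#'
#' @param x A `zooms_id` object or its `results` tibble.
#' @param truth A tibble with `sample_id`, `manual_taxon`, and optionally
#'   `manual_family`, `manual_order`, `site`.
#' @return A `zooms_eval` object: list with `pairs` (per-sample join),
#'   `per_site`, `weighted`, `confusion`, `ttest`, `n_excluded_fails`.
#' @export
evaluate_identifications <- function(x, truth) {
  results <- if (inherits(x, "zooms_id")) x$results else x
  if (!all(c("sample_id", "manual_taxon") %in% names(truth))) {
    stop("`truth` needs columns sample_id and manual_taxon", call. = FALSE)
  }
  if (!"site" %in% names(truth)) {
    truth$site <- "all"
  }
  top <- results |>
    dplyr::filter(is.na(.data$rank) | .data$rank == 1) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      pred_taxon = paste(stats::na.omit(unique(.data$zooms_taxon)), collapse = "|"),
      pred_family = paste(stats::na.omit(unique(.data$family)), collapse = "|"),
      pred_order = paste(stats::na.omit(unique(.data$order)), collapse = "|"),
      correlation = dplyr::first(.data$correlation),
      status = dplyr::first(.data$status),
      .groups = "drop"
    )
  pairs <- top |>
    dplyr::inner_join(truth, by = "sample_id")
  pred_fail <- pairs$status == "fail" | is_fail_label(pairs$pred_taxon)
  truth_fail <- is_fail_label(pairs$manual_taxon)
  n_fails <- sum(pred_fail | truth_fail)
  pairs <- pairs[!(pred_fail | truth_fail), , drop = FALSE]
  if (!nrow(pairs)) {
    stop("no non-fail pairs to evaluate", call. = FALSE)
  }
  match_any <- function(pred, ref) {
    # rank-1 ties are "|"-joined; a sample matches if any tied label does
    purrr::map2_lgl(stringr::str_split(pred, "\\|"), ref, function(p, r) {
      any(is_match(p, rep(r, length(p))))
    })
  }
  pairs$match_taxon <- match_any(pairs$pred_taxon, pairs$manual_taxon)
  levels_avail <- c(taxon = TRUE,
                    family = "manual_family" %in% names(pairs),
                    order = "manual_order" %in% names(pairs))
  if (levels_avail[["family"]]) {
    pairs$match_family <- match_any(pairs$pred_family, pairs$manual_family)
  }
  if (levels_avail[["order"]]) {
    pairs$match_order <- match_any(pairs$pred_order, pairs$manual_order)
  }
  per_site <- purrr::map(names(levels_avail)[levels_avail], function(lvl) {
    pairs |>
      dplyr::group_by(.data$site) |>
      dplyr::summarise(
        level = lvl,
        n = dplyr::n(),
        accuracy = 100 * mean(.data[[paste0("match_", lvl)]]),
        .groups = "drop"
      )
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("site", "level", "n", "accuracy")
  weighted <- per_site |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(accuracy = weighted_accuracy(.data$n, .data$accuracy),
                     n = sum(.data$n),
                     .groups = "drop") |>
    dplyr::select("level", "n", "accuracy")
  first_pred <- vapply(stringr::str_split(pairs$pred_taxon, "\\|"), `[[`,
                       "", 1L)
  confusion <- confusion_matrix(first_pred, pairs$manual_taxon)
  ttest <- NULL
  if (sum(pairs$match_taxon) >= 2 && sum(!pairs$match_taxon) >= 2 &&
      !all(is.na(pairs$correlation))) {
    ttest <- ttest_scores(pairs$correlation[pairs$match_taxon],
                          pairs$correlation[!pairs$match_taxon])
  }
  structure(
    list(pairs = as_tibble(pairs), per_site = per_site, weighted = weighted,
         confusion = confusion, ttest = ttest, n_excluded_fails = n_fails),
    class = "zooms_eval"
  )
}

#' @export
print.zooms_eval <- function(x, ...) {
  cat("<zooms_eval>", nrow(x$pairs), "evaluated pairs (",
      x$n_excluded_fails, "fails excluded )\n")
  print(x$weighted)
  if (!is.null(x$ttest)) {
    cat(sprintf("true vs false scores: t = %.3f, p = %.4g\n",
                x$ttest$t, x$ttest$p_value))
  }
  invisible(x)
}
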