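# Correlation-based taxonomic identification.
#
# A sample's de-isotoped peak list is turned into a binary indicator over a
# fixed m/z grid and Gaussian-smoothed; each reference species is turned
# into a binary window vector (one in every bin whose center lies within
# -0.3/+1.3 Da of one of the species' marker masses). Candidates are ranked
# by the Pearson correlation between the two vectors.

#' Identification parameters
#'
#' @param grid_lo,grid_hi Mass range of the discretization grid, Da.
#' @param bin_width Grid bin width, Da.
#' @param sigma_bins Standard deviation, in bins, of the Gaussian used to
#'   smooth the sample indicator vector before correlating.
#' @param window Match window around each reference mass, Da. The default
#'   `c(-0.3, 1.3)` combines the instrument's +/-0.3 Da accuracy with the
#'   +1 Da shift that deamidation can add to a peptide mass.
#' @param n_top Number of top-ranked candidate species reported; candidates
#'   tied with the last reported rank are all retained.
#' @return A classed parameter list.
#' @export
identify_config <- function(grid_lo = 800, grid_hi = 3700, bin_width = 0.1,
                            sigma_bins = 2, window = c(-0.3, 1.3),
                            n_top = 3L) {
  if (grid_lo >= grid_hi || bin_width <= 0) {
    stop("need grid_lo < grid_hi and bin_width > 0", call. = FALSE)
  }
  if (length(window) != 2 || window[1] >= window[2]) {
    stop("`window` must be an increasing pair c(lo, hi)", call. = FALSE)
  }
  if (sigma_bins < 0) {
    stop("`sigma_bins` must be non-negative", call. = FALSE)
  }
  structure(
    list(grid_lo = grid_lo, grid_hi = grid_hi, bin_width = bin_width,
         sigma_bins = sigma_bins, window = window, n_top = as.integer(n_top)),
    class = "zooms_identify_config"
  )
}

#' Build a mass discretization grid
#'
#' Bins are half-open intervals `[lo + k w, lo + (k + 1) w)`; a mass lying
#' exactly on a boundary belongs to the higher bin.
#'
#' @param lo,hi Mass range, Da (`lo < hi`).
#' @param bin_width Bin width, Da (positive).
#' @return A `zooms_grid` list with `lo`, `hi`, `bin_width`, `n_bins`.
#' @export
build_grid <- function(lo = 800, hi = 3700, bin_width = 0.1) {
  if (!is.finite(bin_width) || bin_width <= 0) {
    stop("`bin_width` must be positive", call. = FALSE)
  }
  if (lo >= hi) {
    stop("need lo < hi", call. = FALSE)
  }
  structure(
    list(lo = lo, hi = hi, bin_width = bin_width,
         n_bins = as.integer(ceiling((hi - lo) / bin_width))),
    class = "zooms_grid"
  )
}

grid_centers <- function(grid) {
  grid$lo + (seq_len(grid$n_bins) - 0.5) * grid$bin_width
}

grid_bin <- function(grid, mass) {
  as.integer(floor((mass - grid$lo) / grid$bin_width)) + 1L
}

#' Reference window vector
#'
#' Binary vector over the grid: a bin is one iff its center lies within
#' `[m + window[1], m + window[2]]` for some marker mass `m` of the
#' species. Overlapping windows union to one.
#'
#' @param masses Numeric marker masses of one species, Da.
#' @param grid A [build_grid()] result.
#' @param window Match window, Da.
#' @return A binary numeric vector of length `grid$n_bins`.
#' @export
vectorize_reference <- function(masses, grid, window = c(-0.3, 1.3)) {
  v <- numeric(grid$n_bins)
  masses <- masses[is.finite(masses)]
  if (!length(masses)) {
    warning("species has no reference markers; returning a zero vector",
            call. = FALSE)
    return(v)
  }
  # bin k has center lo + (k - 0.5) w; solve for centers inside the window
  k_lo <- ceiling((masses + window[1] - grid$lo) / grid$bin_width + 0.5)
  k_hi <- floor((masses + window[2] - grid$lo) / grid$bin_width + 0.5)
  for (i in seq_along(masses)) {
    a <- max(1L, k_lo[i])
    b <- min(grid$n_bins, k_hi[i])
    if (a <= b) v[a:b] <- 1
  }
  v
}

#' Sample indicator vector
#'
#' Binary vector with a one in the bin containing each peak mass. Peaks
#' outside the grid range are dropped with a warning.
#'
#' @param peak_mz Numeric peak masses, Da.
#' @param grid A [build_grid()] result.
#' @return A binary numeric vector of length `grid$n_bins`.
#' @export
vectorize_sample <- function(peak_mz, grid) {
  v <- numeric(grid$n_bins)
  inside <- peak_mz >= grid$lo & peak_mz < grid$hi
  if (any(!inside)) {
    warning(sum(!inside), " peak(s) outside the [", grid$lo, ", ", grid$hi,
            ") Da grid were dropped", call. = FALSE)
  }
  v[grid_bin(grid, peak_mz[inside])] <- 1
  v
}

#' Gaussian smoothing of an indicator vector
#'
#' Discrete Gaussian convolution with a kernel truncated at six standard
#' deviations. Mass spilling over the vector ends is reflected back, so the
#' total mass is preserved exactly; `sigma_bins = 0` is the identity.
#'
#' @param v Numeric vector.
#' @param sigma_bins Kernel standard deviation in bins (non-negative).
#' @return A numeric vector of the same length.
#' @export
smooth_vector <- function(v, sigma_bins = 2) {
  if (sigma_bins < 0) {
    stop("`sigma_bins` must be non-negative", call. = FALSE)
  }
  if (sigma_bins == 0 || !length(v)) {
    return(v)
  }
  r <- as.integer(ceiling(6 * sigma_bins))
  kern <- dnorm(seq(-r, r), sd = sigma_bins)
  kern <- kern / sum(kern)
  n <- length(v)
  padded <- c(numeric(2 * r), v, numeric(2 * r))
  full <- as.numeric(stats::filter(padded, kern, method = "convolution",
                                   sides = 2))
  core <- full[(2 * r + 1):(2 * r + n)]
  # reflect spill-over back inside so sum(v) is conserved exactly
  left <- full[(r + 1):(2 * r)]        # virtual bins -r+1 .. 0, ascending
  right <- full[(2 * r + n + 1):(3 * r + n)]  # virtual bins n+1 .. n+r
  for (k in seq_len(min(r, n))) {
    core[k] <- core[k] + left[r - k + 1]
    core[n - k + 1] <- core[n - k + 1] + right[k]
  }
  core
}

#' Pearson correlation of two score vectors
#'
#' @param a,b Equal-length numeric vectors (typically the smoothed sample
#'   vector and a reference window vector).
#' @return The Pearson correlation; if either vector has zero variance the
#'   score is 0 and carries attribute `degenerate = TRUE`.
#' @export
correlate_vectors <- function(a, b) {
  if (length(a) != length(b)) {
    stop("vectors must have equal length (", length(a), " vs ", length(b),
         ")", call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    message("degenerate correlation: a constant vector scores 0")
    return(structure(0, degenerate = TRUE))
  }
  cor(a, b)
}

#' Match sample peaks to a species' markers
#'
#' For each reference marker mass, the closest sample peak whose delta
#' (peak minus marker) lies in the match window yields a matched marker.
#' Assignment is one-to-one and greedy by absolute delta, so a peak is
#' never counted for two markers of the same species.
#'
#' @param peak_mz Numeric sample peak masses, Da.
#' @param markers A tibble with columns `marker_id` and `mass` for one
#'   species.
#' @param window Match window, Da.
#' @return A tibble `marker_id`, `ref_mass`, `sample_mass`, `delta`.
#' @export
match_markers <- function(peak_mz, markers, window = c(-0.3, 1.3)) {
  empty <- tibble(marker_id = character(), ref_mass = numeric(),
                  sample_mass = numeric(), delta = numeric())
  if (!length(peak_mz) || !nrow(markers)) {
    return(empty)
  }
  delta <- outer(peak_mz, markers$mass, `-`)
  ok <- which(delta >= window[1] & delta <= window[2], arr.ind = TRUE)
  if (!nrow(ok)) {
    return(empty)
  }
  cand <- tibble(
    peak = ok[, 1],
    marker = ok[, 2],
    delta = delta[ok]
  ) |>
    dplyr::arrange(abs(.data$delta), .data$delta)
  used_peak <- logical(length(peak_mz))
  used_marker <- logical(nrow(markers))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    p <- cand$peak[i]
    m <- cand$marker[i]
    if (!used_peak[p] && !used_marker[m]) {
      used_peak[p] <- TRUE
      used_marker[m] <- TRUE
      keep[i] <- TRUE
    }
  }
  cand <- cand[keep, ]
  tibble(
    marker_id = markers$marker_id[cand$marker],
    ref_mass = markers$mass[cand$marker],
    sample_mass = peak_mz[cand$peak],
    delta = cand$delta
  ) |>
    dplyr::arrange(.data$ref_mass)
}

#' Scan peaks for known contaminants
#'
#' Flags every (contaminant mass, sample peak) pair whose delta lies in the
#' match window, aggregating contaminant names per sample.
#'
#' @param peaks A peaks tibble with `sample_id` and `mz`.
#' @param contaminants A tibble `name`, `mass` from [read_contaminants()].
#' @param window Match window, Da (the marker window is reused).
#' @return A tibble `sample_id`, `contaminant`, `ref_mass`, `sample_mass`.
#' @export
scan_contaminants <- function(peaks, contaminants, window = c(-0.3, 1.3)) {
  empty <- tibble(sample_id = character(), contaminant = character(),
                  ref_mass = numeric(), sample_mass = numeric())
  if (is.null(contaminants) || !nrow(contaminants) || !nrow(peaks)) {
    return(empty)
  }
  delta <- outer(peaks$mz, contaminants$mass, `-`)
  ok <- which(delta >= window[1] & delta <= window[2], arr.ind = TRUE)
  if (!nrow(ok)) {
    return(empty)
  }
  tibble(
    sample_id = peaks$sample_id[ok[, 1]],
    contaminant = contaminants$name[ok[, 2]],
    ref_mass = contaminants$mass[ok[, 2]],
    sample_mass = peaks$mz[ok[, 1]]
  ) |>
    dplyr::arrange(.data$sample_id, .data$contaminant, .data$ref_mass)
}

#' Identification status from matched-marker count
#'
#' Identifications resting on four or fewer peptide markers are unreliable
#' and flagged for manual inspection; with no matched marker at all the
#' sample is a fail.
#'
#' @param n_markers Integer vector of distinct matched-marker counts.
#' @return Character vector: `"fail"` (0 markers), `"tentative"` (1-4) or
#'   `"ok"` (5 or more).
#' @export
classify_status <- function(n_markers) {
  n_markers <- ifelse(is.na(n_markers), 0L, n_markers)
  dplyr::case_when(
    n_markers <= 0 ~ "fail",
    n_markers <= 4 ~ "tentative",
    TRUE ~ "ok"
  )
}

# Species-level view of a reference partition: one row per species with its
# lineage and marker table.
species_records <- function(db) {
  parts <- split(db, db$species)
  tibble(
    species = names(parts),
    zooms_taxon = unname(vapply(parts, function(d) d$zooms_taxon[1],
                                character(1))),
    family = unname(vapply(parts, function(d) as.character(d$family[1]),
                           character(1))),
    order = unname(vapply(parts, function(d) as.character(d$order[1]),
                          character(1))),
    markers = unname(lapply(parts, function(d) {
      tibble(marker_id = d$marker_id, mass = d$mass)
    }))
  )
}

identify_one <- function(peak_mz, sp, ref_mat, grid, cfg) {
  if (!length(peak_mz)) {
    cand <- sp[0, c("species", "zooms_taxon", "family", "order")]
    cand$correlation <- numeric(0)
    cand$rank <- integer(0)
    cand$matched_markers <- list()
    cand$n_matched_markers <- integer(0)
    return(list(candidates = cand, status = "fail"))
  }
  svec <- smooth_vector(vectorize_sample(peak_mz, grid), cfg$sigma_bins)
  corr <- vapply(seq_len(nrow(sp)), function(j) {
    as.numeric(suppressMessages(correlate_vectors(svec, ref_mat[, j])))
  }, numeric(1))
  cand <- sp |>
    dplyr::select("species", "zooms_taxon", "family", "order") |>
    dplyr::mutate(correlation = corr,
                  rank = dplyr::min_rank(dplyr::desc(corr))) |>
    dplyr::filter(.data$rank <= cfg$n_top) |>
    dplyr::arrange(.data$rank, .data$species)
  matched <- purrr::map(cand$species, function(s) {
    match_markers(peak_mz, sp$markers[[match(s, sp$species)]],
                  window = cfg$window)
  })
  cand$matched_markers <- matched
  cand$n_matched_markers <- vapply(matched, function(m) {
    dplyr::n_distinct(m$marker_id)
  }, integer(1))
  top_n <- if (any(cand$rank == 1)) {
    max(cand$n_matched_markers[cand$rank == 1])
  } else 0L
  list(candidates = cand, status = classify_status(top_n))
}

#' Identify the taxa of one or more samples
#'
#' Scores each sample's peak list against every species of a reference
#' partition, ranks candidates by correlation (ties share a rank and are
#' all reported, even beyond `n_top`), attaches matched markers and
#' contaminant hits, and assigns a per-sample status: `"ok"` (top candidate
#' supported by at least five distinct markers), `"tentative"` (1-4) or
#' `"fail"` (no peaks or no matched marker).
#'
#' @param peaks A peaks tibble (`sample_id`, `mz`, ...), typically from
#'   [preprocess_spectra()]. Samples recorded as failed in its
#'   `"sample_status"` attribute are carried through as fails.
#' @param db A cleaned reference tibble (one region's partition).
#' @param contaminants Optional contaminant tibble (`name`, `mass`).
#' @param cfg An [identify_config()].
#' @return A `zooms_id` object: list with `results` (one row per sample and
#'   candidate: species, lineage, correlation, rank, matched markers,
#'   status), `contaminant_hits`, and `cfg`.
#' @export
identify_taxa <- function(peaks, db, contaminants = NULL,
                          cfg = identify_config()) {
  if (is.null(db) || !nrow(db)) {
    stop("empty reference database", call. = FALSE)
  }
  if (!all(c("sample_id", "mz") %in% names(peaks))) {
    stop("`peaks` needs columns sample_id and mz", call. = FALSE)
  }
  grid <- build_grid(cfg$grid_lo, cfg$grid_hi, cfg$bin_width)
  sp <- species_records(db)
  ref_mat <- vapply(sp$markers, function(m) {
    vectorize_reference(m$mass, grid, window = cfg$window)
  }, numeric(grid$n_bins))
  status_in <- attr(peaks, "sample_status")
  samples <- unique(c(peaks$sample_id,
                      if (!is.null(status_in)) status_in$sample_id))
  empty_results <- tibble(
    sample_id = character(), species = character(),
    zooms_taxon = character(), family = character(), order = character(),
    correlation = numeric(), rank = integer(), matched_markers = list(),
    n_matched_markers = integer(), status = character()
  )
  peak_sets <- split(peaks$mz, factor(peaks$sample_id, levels = samples))
  res <- purrr::map(samples, function(sid) {
    one <- identify_one(peak_sets[[sid]], sp, ref_mat, grid, cfg)
    if (nrow(one$candidates)) {
      dplyr::bind_cols(tibble(sample_id = sid), one$candidates) |>
        dplyr::mutate(status = one$status)
    } else {
      tibble(sample_id = sid, species = NA_character_,
             zooms_taxon = NA_character_, family = NA_character_,
             order = NA_character_, correlation = NA_real_,
             rank = NA_integer_, matched_markers = list(NULL),
             n_matched_markers = NA_integer_, status = "fail")
    }
  }) |>
    (\(x) dplyr::bind_rows(empty_results, x))() |>
    dplyr::arrange(.data$sample_id, .data$rank, .data$species)
  hits <- scan_contaminants(peaks, contaminants, window = cfg$window)
  structure(
    list(results = res, contaminant_hits = hits, cfg = cfg,
         region = attr(db, "region_label")),
    class = "zooms_id"
  )
}

#' Identify a single sample
#'
#' Convenience wrapper around [identify_taxa()] for a peak list belonging
#' to one sample.
#'
#' @param peaks A peaks tibble for one sample, or a numeric vector of peak
#'   masses.
#' @param sample_id Sample identifier used when `peaks` is a bare numeric
#'   vector.
#' @inheritParams identify_taxa
#' @return A `zooms_id` object (see [identify_taxa()]).
#' @export
identify_sample <- function(peaks, db, contaminants = NULL,
                            cfg = identify_config(), sample_id = "sample") {
  if (is.numeric(peaks)) {
    peaks <- tibble(sample_id = sample_id, mz = as.numeric(peaks))
  }
  if (dplyr::n_distinct(peaks$sample_id) > 1) {
    stop("`identify_sample()` expects a single sample; use identify_taxa()",
         call. = FALSE)
  }
  identify_taxa(peaks, db, contaminants = contaminants, cfg = cfg)
}

serialize_markers <- function(m) {
  if (is.null(m) || !nrow(m)) {
    return("")
  }
  paste(sprintf("%s:%.4f:%.4f", m$marker_id, m$ref_mass, m$sample_mass),
        collapse = ";")
}

#' Export identification results to CSV
#'
#' Writes the two batch output files: a results table (one row per sample
#' and candidate, matched markers serialized as
#' `marker_id:ref_mass:sample_mass;...`) and a contaminant table (one row
#' per hit). Row order is deterministic (sample, rank, species).
#'
#' @param x A `zooms_id` object.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix, default `"zoomsid"`.
#' @return Invisibly, a character vector with the two file paths
#'   (`results`, `contaminants`).
#' @export
write_results <- function(x, dir, prefix = "zoomsid") {
  stopifnot(inherits(x, "zooms_id"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- x$results |>
    dplyr::mutate(
      matched_markers = vapply(.data$matched_markers, serialize_markers,
                               character(1)),
      correlation = round(.data$correlation, 6)
    ) |>
    dplyr::select("sample_id", "rank", "species", "zooms_taxon", "family",
                  "order", "correlation", "n_matched_markers",
                  "matched_markers", "status") |>
    dplyr::arrange(.data$sample_id, .data$rank, .data$species)
  results_path <- file.path(dir, paste0(prefix, "_results.csv"))
  contam_path <- file.path(dir, paste0(prefix, "_contaminants.csv"))
  readr::write_csv(res, results_path)
  readr::write_csv(x$contaminant_hits, contam_path)
  invisible(c(results = results_path, contaminants = contam_path))
}

#' Batch identification with CSV export
#'
#' Runs [identify_taxa()] on a batch of peak lists and writes the results
#' and contaminants CSV files. Repeated runs on identical inputs produce
#' byte-identical files.
#'
#' @inheritParams identify_taxa
#' @param out_dir Output directory.
#' @param prefix Output file prefix.
#' @return The `zooms_id` object, invisibly, with the written paths in its
#'   `paths` element.
#' @export
run_batch <- function(peaks, db, contaminants = NULL,
                      cfg = identify_config(), out_dir, prefix = "zoomsid") {
  if (!nrow(peaks) && is.null(attr(peaks, "sample_status"))) {
    stop("no samples to identify", call. = FALSE)
  }
  x <- identify_taxa(peaks, db, contaminants = contaminants, cfg = cfg)
  x$paths <- write_results(x, out_dir, prefix = prefix)
  invisible(x)
}

#' @export
print.zooms_id <- function(x, ...) {
  n_samples <- dplyr::n_distinct(x$results$sample_id)
  cat("<zooms_id> identifications for", n_samples, "sample(s)\n")
  if (!is.null(x$region)) cat("  region:", x$region, "\n")
  top <- x$results |>
    dplyr::filter(is.na(.data$rank) | .data$rank == 1) |>
    dplyr::select("sample_id", "species", "zooms_taxon", "correlation",
                  "n_matched_markers", "status")
  print(top, n = 20)
  if (nrow(x$contaminant_hits)) {
    cat("contaminant hits:", nrow(x$contaminant_hits), "\n")
  }
  invisible(x)
}
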