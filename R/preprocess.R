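# Preprocessing chain: each raw technical replicate is smoothed
# (Savitzky-Golay), baseline-corrected (SNIP), intensity-calibrated (TIC),
# noise-estimated, peak-picked and de-isotoped; low-quality replicates are
# dropped, survivors averaged, and picking/de-isotoping repeated on the
# averaged profile.

#' Preprocessing parameters
#'
#' Bundles every tunable of the preprocessing chain. All values can be
#' overridden per call; the defaults are chosen for MALDI-ToF collagen
#' fingerprints sampled at a few hundredths of a Da per point.
#'
#' @param sg_half_window Savitzky-Golay half window, in points. The filter
#'   window is `2 * sg_half_window + 1` points wide.
#' @param sg_poly_order Savitzky-Golay polynomial order; must be smaller
#'   than the window width.
#' @param snip_iterations Number of SNIP clipping iterations; also the
#'   largest clipping half-window in points (the window decreases to 1).
#' @param snr_threshold Minimum signal-to-noise ratio for a detected peak,
#'   with noise measured as the robust local 1-sigma level (see
#'   [estimate_noise()]). Because a spectrum holds on the order of 1e5
#'   points, a 3-sigma cut would pass dozens of pure-noise maxima per
#'   spectrum; 6 keeps the expected number of false peaks per spectrum well
#'   below one while still passing peaks of modest height.
#' @param peak_half_window Half window, in points, within which a peak must
#'   be the local maximum.
#' @param mono_distance Expected spacing of isotopic satellites, Da.
#' @param mono_tolerance Relative mass tolerance when chaining satellites.
#' @param mono_size_range Integer vector `c(min, max)`: isotopic cluster
#'   sizes considered for collapsing.
#' @param mono_min_cor Minimum Pearson correlation between observed cluster
#'   intensities and the modelled (Poisson-averagine) isotopic pattern for
#'   the cluster to be collapsed to its monoisotopic member.
#' @param replicate_min_peaks Replicates with fewer de-isotoped peaks than
#'   this are dropped.
#' @param replicate_median_fraction Replicates with fewer peaks than this
#'   fraction of the per-sample median peak count are dropped.
#' @return A classed list of parameters.
#' @export
preprocess_config <- function(sg_half_window = 10L,
                              sg_poly_order = 3L,
                              snip_iterations = 100L,
                              snr_threshold = 6,
                              peak_half_window = 20L,
                              mono_distance = 1.00235,
                              mono_tolerance = 1e-4,
                              mono_size_range = c(2L, 10L),
                              mono_min_cor = 0.95,
                              replicate_min_peaks = 5L,
                              replicate_median_fraction = 0.5) {
  cfg <- list(
    sg_half_window = as.integer(sg_half_window),
    sg_poly_order = as.integer(sg_poly_order),
    snip_iterations = as.integer(snip_iterations),
    snr_threshold = snr_threshold,
    peak_half_window = as.integer(peak_half_window),
    mono_distance = mono_distance,
    mono_tolerance = mono_tolerance,
    mono_size_range = as.integer(mono_size_range),
    mono_min_cor = mono_min_cor,
    replicate_min_peaks = as.integer(replicate_min_peaks),
    replicate_median_fraction = replicate_median_fraction
  )
  scalars <- cfg[setdiff(names(cfg), "mono_size_range")]
  if (any(vapply(scalars, function(x) length(x) != 1 || is.na(x) || x <= 0,
                 logical(1)))) {
    stop("all preprocessing parameters must be single positive values",
         call. = FALSE)
  }
  if (length(cfg$mono_size_range) != 2 ||
      cfg$mono_size_range[1] < 1 ||
      cfg$mono_size_range[2] < cfg$mono_size_range[1]) {
    stop("`mono_size_range` must be an increasing pair of positive integers",
         call. = FALSE)
  }
  if (cfg$sg_poly_order >= 2 * cfg$sg_half_window + 1) {
    stop("`sg_poly_order` must be smaller than the Savitzky-Golay window ",
         "(2 * sg_half_window + 1)", call. = FALSE)
  }
  if (cfg$mono_min_cor > 1) {
    stop("`mono_min_cor` must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$replicate_median_fraction > 1) {
    stop("`replicate_median_fraction` must lie in (0, 1]", call. = FALSE)
  }
  structure(cfg, class = "zooms_preprocess_config")
}

#' @export
print.zooms_preprocess_config <- function(x, ...) {
  cat("<zooms preprocessing config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-26s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' Savitzky-Golay smoothing
#'
#' Replaces each intensity by the value of a local least-squares polynomial
#' fit, removing high-frequency noise while preserving peak apex positions.
#' Negative fitted values are clamped to zero.
#'
#' @param spectra A spectra tibble.
#' @param cfg A [preprocess_config()].
#' @return The spectra tibble with smoothed intensities.
#' @export
smooth_spectra <- function(spectra, cfg = preprocess_config()) {
  check_spectra(spectra)
  per_spectrum(spectra, function(d) {
    n <- nrow(d)
    if (n <= 2 * cfg$sg_half_window) {
      stop("spectrum of length ", n, " is shorter than the smoothing window (",
           2 * cfg$sg_half_window + 1, " points)", call. = FALSE)
    }
    y <- signal::sgolayfilt(d$intensity, p = cfg$sg_poly_order,
                            n = 2L * cfg$sg_half_window + 1L)
    d$intensity <- pmax(y, 0)
    d
  })
}

#' SNIP baseline removal
#'
#' Estimates the slowly varying baseline by iterative peak clipping with a
#' decreasing window (SNIP) and subtracts it. Output intensities are
#' non-negative; peak heights above the local baseline are preserved.
#'
#' @inheritParams smooth_spectra
#' @return The spectra tibble with the baseline subtracted.
#' @export
remove_baseline <- function(spectra, cfg = preprocess_config()) {
  check_spectra(spectra)
  per_spectrum(spectra, function(d) {
    b <- snip_baseline_cpp(d$intensity, cfg$snip_iterations)
    d$intensity <- pmax(d$intensity - b, 0)
    d
  })
}

#' Total-ion-current calibration
#'
#' Divides each spectrum's intensities by their sum so every spectrum
#' carries unit total ion current, making replicates and samples
#' comparable.
#'
#' @inheritParams smooth_spectra
#' @return The spectra tibble with intensities summing to one per spectrum.
#' @export
normalize_tic <- function(spectra) {
  check_spectra(spectra)
  per_spectrum(spectra, function(d) {
    s <- sum(d$intensity)
    if (!is.finite(s) || s <= 0) {
      stop("cannot TIC-normalize a spectrum with zero total intensity",
           call. = FALSE)
    }
    d$intensity <- d$intensity / s
    d
  })
}

# Robust local noise statistics of one intensity vector, per chunk and
# interpolated to every point:
#   level - the chunk median, i.e. the center of the local noise band
#           (baseline removal leaves a small positive noise floor);
#   noise - the 84th-percentile-minus-median distance, one sigma for
#           Gaussian noise and still a 1-sigma estimate after negatives
#           have been clamped to zero.
# Both are robust to sparse peaks, which only move quantiles above the
# 84th. Chunks are equal-sized so no chunk degenerates to a few points.
local_noise_stats <- function(y, floor_eps = 1e-12) {
  n <- length(y)
  target <- min(max(256L, n %/% 50L), 4096L)
  n_chunks <- max(1L, as.integer(round(n / target)))
  bounds <- round(seq(0, n, length.out = n_chunks + 1))
  centers <- med <- q84 <- numeric(n_chunks)
  for (k in seq_len(n_chunks)) {
    lo <- bounds[k] + 1
    hi <- bounds[k + 1]
    centers[k] <- (lo + hi) / 2
    qq <- quantile(y[lo:hi], c(0.5, 0.84), names = FALSE, type = 8)
    med[k] <- qq[1]
    q84[k] <- qq[2]
  }
  interp <- function(v) {
    if (n_chunks == 1) {
      rep(v, n)
    } else {
      approx(x = centers, y = v, xout = seq_len(n), rule = 2)$y
    }
  }
  list(level = interp(med),
       noise = pmax(interp(q84 - med), floor_eps))
}

local_noise <- function(y, floor_eps = 1e-12) {
  local_noise_stats(y, floor_eps)$noise
}

#' Local noise estimation
#'
#' Estimates the local noise level (a robust 1-sigma equivalent) along each
#' spectrum by a windowed quantile-distance estimator: within each chunk of
#' points the noise is the distance from the median to the 84th percentile,
#' which equals one standard deviation for Gaussian noise and stays
#' unbiased after negative values have been clamped to zero. Chunk values
#' are linearly interpolated to every m/z position and floored at a small
#' positive constant.
#'
#' @inheritParams smooth_spectra
#' @return A tibble `sample_id`, `replicate`, `mz`, `noise`.
#' @export
estimate_noise <- function(spectra) {
  check_spectra(spectra)
  spectra |>
    dplyr::group_by(.data$sample_id, .data$replicate) |>
    dplyr::group_modify(function(d, key) {
      tibble(mz = d$mz, noise = local_noise(d$intensity))
    }) |>
    dplyr::ungroup()
}

#' Peak detection
#'
#' Finds local maxima within `peak_half_window` points whose intensity is at
#' least `snr_threshold` times the local noise level.
#'
#' @inheritParams smooth_spectra
#' @param noise Optional precomputed noise tibble from [estimate_noise()];
#'   estimated on the fly when `NULL`.
#' @return A peaks tibble `sample_id`, `replicate`, `mz`, `intensity`,
#'   `snr` (possibly zero rows).
#' @export
detect_peaks <- function(spectra, cfg = preprocess_config(), noise = NULL) {
  check_spectra(spectra)
  if (!is.null(noise)) {
    noise_tbl <- noise |>
      dplyr::select("sample_id", "replicate", "mz", "noise")
    spectra <- spectra |>
      dplyr::left_join(noise_tbl, by = c("sample_id", "replicate", "mz"))
    if (anyNA(spectra$noise)) {
      stop("`noise` does not cover every point of `spectra`", call. = FALSE)
    }
  }
  spectra |>
    dplyr::group_by(.data$sample_id, .data$replicate) |>
    dplyr::group_modify(function(d, key) {
      stats <- local_noise_stats(d$intensity)
      nz <- if ("noise" %in% names(d)) d$noise else stats$noise
      apex <- local_maxima_cpp(d$intensity, cfg$peak_half_window)
      # exclude apexes whose window is truncated by the spectrum ends
      apex <- apex[apex > cfg$peak_half_window &
                     apex <= nrow(d) - cfg$peak_half_window]
      # signal is measured as the excess over the local noise-band center
      snr <- (d$intensity[apex] - stats$level[apex]) / nz[apex]
      keep <- snr >= cfg$snr_threshold
      tibble(mz = d$mz[apex][keep],
             intensity = d$intensity[apex][keep],
             snr = snr[keep])
    }) |>
    dplyr::ungroup()
}

# Modelled isotopic-envelope abundances for a peptide of monoisotopic mass
# m: Poisson approximation to the averagine isotope distribution, with the
# Poisson mean linear in mass.
isotope_pattern <- function(mass, size) {
  lambda <- max(0.000594 * mass - 0.03091, 1e-6)
  dpois(seq_len(size) - 1L, lambda)
}

#' Monoisotopic peak picking (de-isotoping)
#'
#' Groups detected peaks into isotopic clusters (satellites spaced
#' `mono_distance` apart within a relative `mono_tolerance`), compares each
#' cluster's intensity pattern with the modelled mass-dependent isotopic
#' pattern (Poisson-approximated averagine), and collapses clusters that
#' correlate at least `mono_min_cor` with the model to their lowest-mass
#' (monoisotopic) member. Peaks outside any accepted cluster pass through
#' unchanged, so the output is always a subset of the input.
#'
#' @param peaks A peaks tibble from [detect_peaks()].
#' @param cfg A [preprocess_config()].
#' @return The peaks tibble, possibly with rows removed, plus a logical
#'   `is_monoisotopic` column marking collapsed cluster heads.
#' @export
pick_monoisotopic <- function(peaks, cfg = preprocess_config()) {
  key_cols <- intersect(c("sample_id", "replicate"), names(peaks))
  peaks |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key_cols))) |>
    dplyr::group_modify(function(d, key) pick_mono_one(d, cfg)) |>
    dplyr::ungroup()
}

pick_mono_one <- function(d, cfg) {
  n <- nrow(d)
  if (n == 0) {
    d$is_monoisotopic <- logical(0)
    return(d)
  }
  d <- d[order(d$mz), ]
  keep <- rep(TRUE, n)
  mono <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (!keep[i] || mono[i]) next
    chain <- i
    repeat {
      last <- chain[length(chain)]
      target <- d$mz[last] + cfg$mono_distance
      tol <- cfg$mono_tolerance * target
      cand <- which(keep & abs(d$mz - target) <= tol)
      cand <- cand[cand > last]
      if (!length(cand)) break
      nxt <- cand[which.min(abs(d$mz[cand] - target))]
      chain <- c(chain, nxt)
      if (length(chain) >= cfg$mono_size_range[2]) break
    }
    k <- length(chain)
    if (k >= max(2L, cfg$mono_size_range[1]) && k <= cfg$mono_size_range[2]) {
      model <- isotope_pattern(d$mz[chain[1]], k)
      r <- suppressWarnings(cor(d$intensity[chain], model))
      if (!is.na(r) && r >= cfg$mono_min_cor) {
        keep[chain[-1]] <- FALSE
        mono[chain[1]] <- TRUE
      }
    }
  }
  out <- d[keep, ]
  out$is_monoisotopic <- mono[keep]
  out
}

#' Replicate quality filter
#'
#' Drops low-quality technical replicates from each sample: a replicate is
#' removed when its de-isotoped peak count falls below
#' `replicate_min_peaks`, or below `replicate_median_fraction` times the
#' median peak count of the sample's replicates. Each drop is reported via
#' `message()`. Samples whose replicates are all dropped are recorded in the
#' `"failed_samples"` attribute of the result.
#'
#' @param peaks A peaks tibble with `sample_id` and `replicate` columns.
#' @param cfg A [preprocess_config()].
#' @return The filtered peaks tibble, with attributes `dropped_replicates`
#'   (tibble of sample_id, replicate, n_peaks) and `failed_samples`
#'   (character).
#' @export
filter_replicate_quality <- function(peaks, cfg = preprocess_config()) {
  counts <- peaks |>
    dplyr::count(.data$sample_id, .data$replicate, name = "n_peaks") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(
      drop = .data$n_peaks < cfg$replicate_min_peaks |
        .data$n_peaks < cfg$replicate_median_fraction * median(.data$n_peaks)
    ) |>
    dplyr::ungroup()
  dropped <- counts |> dplyr::filter(.data$drop)
  for (i in seq_len(nrow(dropped))) {
    message("dropping replicate ", dropped$replicate[i], " of sample '",
            dropped$sample_id[i], "' (", dropped$n_peaks[i], " peaks)")
  }
  kept <- counts |> dplyr::filter(!.data$drop)
  failed <- setdiff(unique(counts$sample_id), unique(kept$sample_id))
  out <- peaks |>
    dplyr::semi_join(kept, by = c("sample_id", "replicate"))
  attr(out, "dropped_replicates") <- dropped |>
    dplyr::select("sample_id", "replicate", "n_peaks")
  attr(out, "failed_samples") <- failed
  out
}

#' Average technical replicates
#'
#' Interpolates each sample's replicates onto the union of their m/z grids
#' (linear interpolation, zero outside a replicate's range) and takes the
#' pointwise mean intensity.
#'
#' @param spectra A spectra tibble (profiles, not peak lists).
#' @return A spectra tibble with one averaged spectrum per sample
#'   (`replicate` set to 1).
#' @export
average_replicates <- function(spectra) {
  check_spectra(spectra)
  if (!nrow(spectra)) {
    stop("cannot average an empty replicate group", call. = FALSE)
  }
  spectra |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(d, key) {
      reps <- split(d, d$replicate)
      if (length(reps) == 1) {
        return(tibble(replicate = 1L, mz = reps[[1]]$mz,
                      intensity = reps[[1]]$intensity))
      }
      grids <- lapply(reps, `[[`, "mz")
      same_grid <- all(vapply(grids[-1], identical, logical(1), grids[[1]]))
      if (same_grid) {
        m <- rowMeans(vapply(reps, `[[`, numeric(length(grids[[1]])),
                             "intensity"))
        return(tibble(replicate = 1L, mz = grids[[1]], intensity = m))
      }
      grid <- sort(unique(unlist(grids)))
      ys <- vapply(reps, function(r) {
        y <- approx(r$mz, r$intensity, xout = grid, rule = 1)$y
        y[is.na(y)] <- 0
        y
      }, numeric(length(grid)))
      tibble(replicate = 1L, mz = grid, intensity = rowMeans(ys))
    }) |>
    dplyr::ungroup()
}

#' Full preprocessing of replicate groups
#'
#' Runs the whole chain per replicate (smooth, SNIP baseline, TIC, noise,
#' peak detection, de-isotoping), drops low-quality replicates, averages the
#' surviving preprocessed profiles, and repeats peak picking and
#' de-isotoping on the averaged spectrum.
#'
#' @param spectra A spectra tibble covering one or more samples with their
#'   technical replicates.
#' @param cfg A [preprocess_config()].
#' @return A peaks tibble (`sample_id`, `mz`, `intensity`, `snr`,
#'   `is_monoisotopic`) holding the final per-sample peak lists. The
#'   `"sample_status"` attribute is a tibble with one row per input sample:
#'   `sample_id`, `n_replicates`, `n_replicates_kept`, `n_peaks`, `failed`.
#'   Samples failing quality control contribute no peak rows and are
#'   flagged `failed = TRUE`.
#' @export
preprocess_spectra <- function(spectra, cfg = preprocess_config()) {
  check_spectra(spectra)
  corrected <- spectra |>
    smooth_spectra(cfg) |>
    remove_baseline(cfg)
  # a replicate with no signal left after baseline removal (e.g. a flat or
  # empty acquisition) cannot be TIC-calibrated; drop it here so it fails
  # quality control rather than aborting the batch
  totals <- corrected |>
    dplyr::group_by(.data$sample_id, .data$replicate) |>
    dplyr::summarise(total = sum(.data$intensity), .groups = "drop")
  dead <- totals |> dplyr::filter(.data$total <= 0)
  for (i in seq_len(nrow(dead))) {
    message("replicate ", dead$replicate[i], " of sample '",
            dead$sample_id[i], "' has no signal; dropping")
  }
  prepared <- corrected |>
    dplyr::anti_join(dead, by = c("sample_id", "replicate"))
  if (nrow(prepared)) {
    prepared <- normalize_tic(prepared)
  }
  rep_peaks <- prepared |>
    detect_peaks(cfg) |>
    pick_monoisotopic(cfg)
  n_reps_in <- spectra |>
    dplyr::distinct(.data$sample_id, .data$replicate) |>
    dplyr::count(.data$sample_id, name = "n_replicates")
  # replicates with zero peaks never appear in rep_peaks; reinstate them as
  # zero-count rows so the quality rule sees them
  all_reps <- spectra |> dplyr::distinct(.data$sample_id, .data$replicate)
  rep_counts <- rep_peaks |>
    dplyr::count(.data$sample_id, .data$replicate, name = "n_peaks") |>
    dplyr::right_join(all_reps, by = c("sample_id", "replicate")) |>
    dplyr::mutate(n_peaks = dplyr::coalesce(.data$n_peaks, 0L))
  qc <- rep_counts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(
      drop = .data$n_peaks < cfg$replicate_min_peaks |
        .data$n_peaks < cfg$replicate_median_fraction * median(.data$n_peaks)
    ) |>
    dplyr::ungroup()
  kept <- qc |> dplyr::filter(!.data$drop)
  for (i in which(qc$drop)) {
    message("dropping replicate ", qc$replicate[i], " of sample '",
            qc$sample_id[i], "' (", qc$n_peaks[i], " peaks)")
  }
  averaged <- prepared |>
    dplyr::semi_join(kept, by = c("sample_id", "replicate"))
  if (nrow(averaged)) {
    final <- averaged |>
      average_replicates() |>
      detect_peaks(cfg) |>
      pick_monoisotopic(cfg) |>
      dplyr::select(-"replicate")
  } else {
    final <- tibble(sample_id = character(), mz = numeric(),
                    intensity = numeric(), snr = numeric(),
                    is_monoisotopic = logical())
  }
  status <- n_reps_in |>
    dplyr::left_join(
      kept |> dplyr::count(.data$sample_id, name = "n_replicates_kept"),
      by = "sample_id"
    ) |>
    dplyr::left_join(
      final |> dplyr::count(.data$sample_id, name = "n_peaks"),
      by = "sample_id"
    ) |>
    dplyr::mutate(
      n_replicates_kept = dplyr::coalesce(.data$n_replicates_kept, 0L),
      n_peaks = dplyr::coalesce(.data$n_peaks, 0L),
      failed = .data$n_replicates_kept == 0L | .data$n_peaks == 0L
    )
  attr(final, "sample_status") <- status
  final
}
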