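# Seeded synthetic ZooMS spectra with known ground truth.
#
# The generator emulates the features of real collagen fingerprints that
# the pipeline must cope with: marker peaks with mass error and optional
# deamidation shifts, isotopic envelopes, a slowly decaying chemical
# baseline, white detector noise, random decoy peaks, contaminant peaks,
# and technical replicates of the same digest.

#' Synthetic-spectrum parameters
#'
#' Defaults describe a well-behaved MALDI-ToF collagen fingerprint:
#' triplicate spots, a profile sampled every 0.02 Da over 800-3700 Da,
#' constant resolving power 10000 (Gaussian peaks, FWHM = m/R), marker
#' peaks 30-100 times the noise level, a decaying baseline, and 30 decoy
#' noise peaks per replicate.
#'
#' @param n_markers Number of the species' markers planted; `NULL` plants
#'   all of them.
#' @param mass_error_sd Per-sample calibration error on each planted mass,
#'   Da (s.d.).
#' @param replicate_jitter_sd Additional per-replicate mass jitter, Da.
#' @param deamidation_prob Probability that a planted marker carries the
#'   deamidation shift.
#' @param deamidation_shift Mass added by deamidation, Da.
#' @param isotope_envelope Plant isotopic satellites at `+k * 1.00235` Da
#'   with Poisson-averagine relative abundances.
#' @param isotope_max_satellites Number of satellites per envelope.
#' @param baseline_amp Baseline amplitude (intensity units) at the low-mass
#'   end; the baseline decays exponentially with mass.
#' @param noise_sd Standard deviation of additive white noise.
#' @param n_noise_peaks Number of random decoy peaks per replicate.
#' @param noise_peak_height Height range of decoy peaks, in units of
#'   `noise_sd`.
#' @param marker_height Height range of planted marker peaks, in units of
#'   `noise_sd`.
#' @param contaminant_names Names from the contaminant table to plant.
#' @param contaminant_height Height range of contaminant peaks, in units
#'   of `noise_sd`.
#' @param n_replicates Technical replicates per sample.
#' @param mz_range,mz_step Profile m/z axis, Da.
#' @param resolving_power Constant resolving power R; peak FWHM is `m / R`.
#' @return A classed parameter list.
#' @export
synth_config <- function(n_markers = NULL,
                         mass_error_sd = 0.05,
                         replicate_jitter_sd = 0.01,
                         deamidation_prob = 0.2,
                         deamidation_shift = 0.984016,
                         isotope_envelope = TRUE,
                         isotope_max_satellites = 3L,
                         baseline_amp = 20,
                         noise_sd = 1,
                         n_noise_peaks = 30L,
                         noise_peak_height = c(2, 40),
                         marker_height = c(30, 100),
                         contaminant_names = character(),
                         contaminant_height = c(10, 40),
                         n_replicates = 3L,
                         mz_range = c(800, 3700),
                         mz_step = 0.02,
                         resolving_power = 10000) {
  cfg <- list(
    n_markers = if (!is.null(n_markers)) as.integer(n_markers),
    mass_error_sd = mass_error_sd,
    replicate_jitter_sd = replicate_jitter_sd,
    deamidation_prob = deamidation_prob,
    deamidation_shift = deamidation_shift,
    isotope_envelope = isotope_envelope,
    isotope_max_satellites = as.integer(isotope_max_satellites),
    baseline_amp = baseline_amp,
    noise_sd = noise_sd,
    n_noise_peaks = as.integer(n_noise_peaks),
    noise_peak_height = noise_peak_height,
    marker_height = marker_height,
    contaminant_names = contaminant_names,
    contaminant_height = contaminant_height,
    n_replicates = as.integer(n_replicates),
    mz_range = mz_range,
    mz_step = mz_step,
    resolving_power = resolving_power
  )
  if (cfg$deamidation_prob < 0 || cfg$deamidation_prob > 1) {
    stop("`deamidation_prob` must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_replicates < 1) {
    stop("`n_replicates` must be at least 1", call. = FALSE)
  }
  if (cfg$mz_step <= 0 || cfg$mz_range[1] >= cfg$mz_range[2]) {
    stop("invalid m/z axis", call. = FALSE)
  }
  structure(cfg, class = "zooms_synth_config")
}

# Add one Gaussian peak to `y` in place-ish; only touches +/- 5 sigma.
add_peak <- function(y, axis_lo, step, n, mass, height, sigma) {
  lo <- max(1L, as.integer(floor((mass - 5 * sigma - axis_lo) / step)) + 1L)
  hi <- min(n, as.integer(ceiling((mass + 5 * sigma - axis_lo) / step)) + 1L)
  if (lo > hi) {
    return(y)
  }
  mz <- axis_lo + (seq(lo, hi) - 1L) * step
  y[lo:hi] <- y[lo:hi] + height * exp(-0.5 * ((mz - mass) / sigma)^2)
  y
}

#' Generate one synthetic sample (all replicates)
#'
#' Plants a subset of the species' reference markers (with per-sample mass
#' error and stochastic deamidation), optional isotopic envelopes, decoy
#' peaks, contaminant peaks, baseline and noise, and renders
#' `cfg$n_replicates` profile replicates. Generation is a pure function of
#' `(db, species, cfg, seed)`.
#'
#' @param db A cleaned reference tibble containing `species`.
#' @param species Species name to plant.
#' @param cfg A [synth_config()].
#' @param seed Integer seed (required for reproducibility; `NULL` uses the
#'   current RNG state).
#' @param sample_id Sample identifier for the emitted spectra.
#' @param contaminants Contaminant tibble (`name`, `mass`), needed when
#'   `cfg$contaminant_names` is nonempty.
#' @return A list with `spectra` (profile tibble, `n_replicates`
#'   replicates) and `truth` (tibble: sample_id, species, marker_id,
#'   ref_mass, deamidated, planted_mass).
#' @export
synth_spectrum <- function(db, species, cfg = synth_config(), seed = NULL,
                           sample_id = "S1", contaminants = NULL) {
  markers <- db[db$species == species, , drop = FALSE]
  if (!nrow(markers)) {
    stop("species '", species, "' is not in the reference database",
         call. = FALSE)
  }
  n_avail <- nrow(markers)
  n_plant <- cfg$n_markers %||% n_avail
  if (n_plant > n_avail) {
    stop("species '", species, "' has only ", n_avail, " markers",
         call. = FALSE)
  }
  with_seed(seed, {
    planted <- markers[sort(sample.int(n_avail, n_plant)), , drop = FALSE]
    deam <- runif(n_plant) < cfg$deamidation_prob
    mass_err <- rnorm(n_plant, 0, cfg$mass_error_sd)
    planted_mass <- planted$mass + ifelse(deam, cfg$deamidation_shift, 0) +
      mass_err
    # heights are expressed in units of the noise level; with noise
    # disabled they fall back to absolute intensity units
    unit <- if (cfg$noise_sd > 0) cfg$noise_sd else 1
    heights <- runif(n_plant, cfg$marker_height[1], cfg$marker_height[2]) *
      unit
    truth <- tibble(
      sample_id = sample_id,
      species = species,
      marker_id = planted$marker_id,
      ref_mass = planted$mass,
      deamidated = deam,
      planted_mass = planted_mass
    )
    cont <- NULL
    if (length(cfg$contaminant_names)) {
      if (is.null(contaminants)) {
        stop("`contaminants` table needed to plant contaminant peaks",
             call. = FALSE)
      }
      cont <- contaminants[contaminants$name %in% cfg$contaminant_names, ,
                           drop = FALSE]
      cont <- cont[cont$mass >= cfg$mz_range[1] &
                     cont$mass <= cfg$mz_range[2], , drop = FALSE]
      cont_height <- runif(nrow(cont), cfg$contaminant_height[1],
                           cfg$contaminant_height[2]) * unit
    }
    axis_lo <- cfg$mz_range[1]
    step <- cfg$mz_step
    n <- as.integer(round(diff(cfg$mz_range) / step)) + 1L
    mz_axis <- axis_lo + (seq_len(n) - 1L) * step
    baseline <- cfg$baseline_amp * exp(-(mz_axis - axis_lo) / 800)
    # decoy (chemical-noise) peaks belong to the digest, not the spot:
    # drawn once per sample, rendered in every replicate
    decoy_mass <- decoy_h <- numeric(0)
    if (cfg$n_noise_peaks > 0) {
      decoy_mass <- runif(cfg$n_noise_peaks, cfg$mz_range[1] + 10,
                          cfg$mz_range[2] - 10)
      decoy_h <- runif(cfg$n_noise_peaks, cfg$noise_peak_height[1],
                       cfg$noise_peak_height[2]) * unit
    }
    reps <- purrr::map(seq_len(cfg$n_replicates), function(r) {
      y <- numeric(n)
      jit <- rnorm(n_plant, 0, cfg$replicate_jitter_sd)
      scale <- runif(n_plant, 0.8, 1.2)
      for (i in seq_len(n_plant)) {
        m <- planted_mass[i] + jit[i]
        sigma <- (m / cfg$resolving_power) / 2.3548
        h <- heights[i] * scale[i]
        if (cfg$isotope_envelope) {
          pat <- isotope_pattern(m, cfg$isotope_max_satellites + 1L)
          rel <- pat / pat[1]
          for (k in seq_along(rel)) {
            y <- add_peak(y, axis_lo, step, n, m + (k - 1) * 1.00235,
                          h * rel[k], sigma)
          }
        } else {
          y <- add_peak(y, axis_lo, step, n, m, h, sigma)
        }
      }
      if (length(decoy_mass)) {
        decoy_scale <- runif(length(decoy_mass), 0.8, 1.2)
        for (i in seq_along(decoy_mass)) {
          sigma <- (decoy_mass[i] / cfg$resolving_power) / 2.3548
          y <- add_peak(y, axis_lo, step, n, decoy_mass[i],
                        decoy_h[i] * decoy_scale[i], sigma)
        }
      }
      if (!is.null(cont) && nrow(cont)) {
        for (i in seq_len(nrow(cont))) {
          sigma <- (cont$mass[i] / cfg$resolving_power) / 2.3548
          y <- add_peak(y, axis_lo, step, n, cont$mass[i], cont_height[i],
                        sigma)
        }
      }
      y <- y + baseline + rnorm(n, 0, cfg$noise_sd)
      tibble(sample_id = sample_id, replicate = r, mz = mz_axis,
             intensity = pmax(y, 0))
    })
    list(spectra = dplyr::bind_rows(reps), truth = truth)
  })
}

#' Generate a seeded synthetic dataset
#'
#' Draws `n_samples` species (uniformly from `species_pool`), generates
#' each sample with [synth_spectrum()] under a per-sample seed derived from
#' `seed`, and optionally writes the replicate spectra as two-column text
#' files plus a `truth.csv`. Identical `(arguments, seed)` give identical
#' output.
#'
#' @param db A cleaned reference tibble.
#' @param n_samples Number of samples.
#' @param cfg A [synth_config()].
#' @param seed Integer master seed.
#' @param species_pool Species to draw from; defaults to all in `db`.
#' @param contaminants Contaminant tibble when contaminant peaks are
#'   configured.
#' @param dir When given, spectra are written under this directory
#'   (`<sample>_<replicate>.txt` and `truth.csv`) and not accumulated in
#'   memory.
#' @return A list with `truth` (all samples) and, when `dir` is `NULL`,
#'   `spectra`.
#' @export
synth_dataset <- function(db, n_samples, cfg = synth_config(), seed = 1L,
                          species_pool = NULL, contaminants = NULL,
                          dir = NULL) {
  species_pool <- species_pool %||% unique(db$species)
  picks <- with_seed(seed, list(
    species = sample(species_pool, n_samples, replace = TRUE),
    seeds = sample.int(.Machine$integer.max - 1L, n_samples)
  ))
  keep <- is.null(dir)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  }
  acc_spec <- if (keep) vector("list", n_samples)
  acc_truth <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    sid <- sprintf("SYN%04d", i)
    one <- synth_spectrum(db, picks$species[i], cfg = cfg,
                          seed = picks$seeds[i], sample_id = sid,
                          contaminants = contaminants)
    acc_truth[[i]] <- one$truth
    if (keep) {
      acc_spec[[i]] <- one$spectra
    } else {
      write_xy_text(one$spectra, dir)
    }
  }
  truth <- dplyr::bind_rows(acc_truth)
  if (!is.null(dir)) {
    readr::write_csv(truth, file.path(dir, "truth.csv"))
  }
  out <- list(truth = truth)
  if (keep) {
    out$spectra <- dplyr::bind_rows(acc_spec)
  }
  out
}
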