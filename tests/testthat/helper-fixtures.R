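# Shared fixtures; the reference DB and contaminant list ship with the
# package, everything else is built in code.

fixture_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) {
      db <<- read_reference_db(zoomsid_example("zooms_markers_synthetic.csv"))
    }
    db
  }
})

fixture_eurasia <- function() {
  partition_by_region(fixture_db(), "Eurasia")
}

fixture_africa <- function() {
  partition_by_region(fixture_db(), "Africa")
}

fixture_contaminants <- local({
  ct <- NULL
  function() {
    if (is.null(ct)) {
      ct <<- read_contaminants(zoomsid_example("contaminants_synthetic.csv"))
    }
    ct
  }
})

# One spectrum tibble from bare vectors.
make_spectrum <- function(mz, intensity, sample_id = "S", replicate = 1L) {
  tibble::tibble(sample_id = sample_id, replicate = as.integer(replicate),
                 mz = mz, intensity = intensity)
}

# Fine-grained profile with Gaussian peaks at `centers`, on [lo, hi].
gauss_profile <- function(lo, hi, step = 0.02, centers = numeric(),
                          heights = 100, sigmas = 0.15, baseline = 0,
                          noise_sd = 0, sample_id = "S", replicate = 1L) {
  mz <- seq(lo, hi, by = step)
  y <- rep(baseline, length(mz))[seq_along(mz)]
  heights <- rep_len(heights, length(centers))
  sigmas <- rep_len(sigmas, length(centers))
  for (i in seq_along(centers)) {
    y <- y + heights[i] * exp(-0.5 * ((mz - centers[i]) / sigmas[i])^2)
  }
  if (noise_sd > 0) {
    y <- y + rnorm(length(mz), 0, noise_sd)
  }
  make_spectrum(mz, pmax(y, 0), sample_id = sample_id, replicate = replicate)
}

# Peaks tibble from bare masses.
make_peaks <- function(mz, sample_id = "S", intensity = 1, snr = 10) {
  tibble::tibble(sample_id = sample_id, mz = mz,
                 intensity = rep_len(intensity, length(mz)),
                 snr = rep_len(snr, length(mz)))
}
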