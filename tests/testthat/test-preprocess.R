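# Naive local least-squares polynomial fit: the independent oracle for
# Savitzky-Golay smoothing (interior points only).
naive_sg <- function(y, half_window, order) {
  n <- length(y)
  out <- y
  for (i in (half_window + 1):(n - half_window)) {
    idx <- (i - half_window):(i + half_window)
    fit <- lm.fit(outer(idx - i, 0:order, `^`), y[idx])
    out[i] <- fit$coefficients[1]
  }
  out
}

test_that("smoothing reproduces low-order polynomials and matches a direct fit", {
  cfg <- preprocess_config(sg_half_window = 5, sg_poly_order = 3)
  mz <- seq(1000, 1010, by = 0.05)
  const <- make_spectrum(mz, rep(4, length(mz)))
  expect_equal(smooth_spectra(const, cfg)$intensity, rep(4, length(mz)),
               tolerance = 1e-9)
  ramp <- make_spectrum(mz, seq(0, 10, length.out = length(mz)))
  sm <- smooth_spectra(ramp, cfg)
  interior <- 20:180
  expect_equal(sm$intensity[interior], ramp$intensity[interior],
               tolerance = 1e-9)

  set.seed(21)
  clean <- 5 + 3 * sin(mz / 2)
  noisy <- make_spectrum(mz, pmax(clean + rnorm(length(mz), 0, 0.1), 0))
  sm2 <- smooth_spectra(noisy, cfg)
  expect_lt(sd((sm2$intensity - clean)[interior]), 0.1)
  # agrees with the brute-force local least-squares fit
  oracle <- naive_sg(noisy$intensity, 5, 3)
  expect_equal(sm2$intensity[interior], pmax(oracle, 0)[interior],
               tolerance = 1e-8)

  short <- make_spectrum(mz[1:5], rep(1, 5))
  expect_error(smooth_spectra(short, cfg), "shorter than")
})

test_that("SNIP removes flat offsets and keeps peak heights", {
  mz <- seq(1000, 1040, by = 0.02)
  zero <- make_spectrum(mz, rep(0, length(mz)))
  expect_equal(remove_baseline(zero)$intensity, rep(0, length(mz)))

  flat <- make_spectrum(mz, rep(40, length(mz)))
  out <- remove_baseline(flat)
  expect_true(all(out$intensity >= 0))
  expect_lt(max(out$intensity), 0.01 * 40)

  # one Gaussian (h = 100) on a linear baseline
  base <- seq(10, 30, length.out = length(mz))
  peak <- 100 * exp(-0.5 * ((mz - 1020) / 0.15)^2)
  sp <- make_spectrum(mz, base + peak)
  rb <- remove_baseline(sp)
  expect_true(all(rb$intensity >= 0))
  apex <- max(rb$intensity)
  expect_lt(abs(apex - 100) / 100, 0.05)
})

test_that("TIC calibration produces unit total intensity", {
  s <- make_spectrum(c(1000, 1001), c(2, 2))
  expect_equal(normalize_tic(s)$intensity, c(0.5, 0.5))
  set.seed(3)
  for (i in 1:5) {
    sp <- make_spectrum(seq(1000, 1010, by = 0.1),
                        abs(rnorm(101, 10, 5)) + 0.1)
    expect_equal(sum(normalize_tic(sp)$intensity), 1, tolerance = 1e-12)
  }
  expect_error(normalize_tic(make_spectrum(c(1000, 1001), c(0, 0))),
               "zero total")
})

test_that("noise estimation recovers the scale of iid noise", {
  set.seed(8)
  mz <- seq(1000, 1100, by = 0.02)
  for (sigma in c(0.5, 2)) {
    s <- make_spectrum(mz, rnorm(length(mz), 100, sigma))
    est <- estimate_noise(s)
    # oracle: residual MAD about the mean
    oracle <- mad(s$intensity - 100)
    expect_lt(abs(median(est$noise) - sigma) / sigma, 0.2)
    expect_lt(abs(median(est$noise) - oracle) / oracle, 0.25)
  }
  zero <- make_spectrum(mz, rep(0, length(mz)))
  expect_true(all(estimate_noise(zero)$noise <= 1e-10))
  spike <- make_spectrum(mz, c(rep(0, 2500), 1000, rep(0, length(mz) - 2501)))
  est <- estimate_noise(spike)
  expect_lt(max(est$noise), 0.01 * 1000)
})

test_that("peak detection finds true peaks and nothing on flat input", {
  set.seed(5)
  cfg <- preprocess_config()
  mz <- seq(1000, 1050, by = 0.02)
  s <- make_spectrum(mz, 100 * exp(-0.5 * ((mz - 1025) / 0.08)^2) +
                       abs(rnorm(length(mz), 0, 1)))
  pk <- detect_peaks(s, cfg)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$mz - 1025), 0.02 + 1e-9)
  expect_gt(pk$snr, cfg$snr_threshold)

  flat <- make_spectrum(mz, rep(7, length(mz)))
  expect_equal(nrow(detect_peaks(flat, cfg)), 0)

  two <- make_spectrum(mz, 80 * exp(-0.5 * ((mz - 1020) / 0.08)^2) +
                         60 * exp(-0.5 * ((mz - 1023) / 0.08)^2) +
                         rnorm(length(mz), 0, 1))
  two$intensity <- pmax(two$intensity, 0)
  pk2 <- detect_peaks(two, cfg)
  # brute-force oracle: strict local maxima over +/- half window
  y <- two$intensity
  hw <- cfg$peak_half_window
  oracle <- vapply((hw + 1):(length(y) - hw), function(i) {
    all(y[i] >= y[(i - hw):(i + hw)]) && y[i] > 0
  }, logical(1))
  oracle_mz <- two$mz[(hw + 1):(length(y) - hw)][oracle]
  expect_true(all(pk2$mz %in% oracle_mz))
  expect_equal(sum(abs(pk2$mz - 1020) < 0.1), 1)
  expect_equal(sum(abs(pk2$mz - 1023) < 0.1), 1)
})

test_that("de-isotoping collapses modelled envelopes to the monoisotopic peak", {
  cfg <- preprocess_config()
  iso <- zoomsid:::isotope_pattern(1453.7, 3)
  pk <- make_peaks(c(1453.7, 1453.7 + 1.00235, 1453.7 + 2.0047),
                   intensity = iso / iso[1])
  out <- pick_monoisotopic(pk, cfg)
  expect_equal(out$mz, 1453.7)
  expect_true(out$is_monoisotopic)

  lone <- make_peaks(2000.0)
  out2 <- pick_monoisotopic(lone, cfg)
  expect_equal(out2$mz, 2000.0)
  expect_false(out2$is_monoisotopic)
})

test_that("the minimum isotopic correlation threshold is honoured", {
  mass <- 1453.7
  model <- zoomsid:::isotope_pattern(mass, 3)
  # construct an observed pattern correlating ~0.92 with the model
  d <- c(1, -2, 1)
  f <- function(t) cor(model + t * d, model) - 0.92
  t_star <- uniroot(f, c(0, 1), tol = 1e-12)$root
  obs <- model + t_star * d
  expect_equal(cor(obs, model), 0.92, tolerance = 1e-6)
  pk <- make_peaks(mass + c(0, 1.00235, 2.0047), intensity = obs)
  # cluster size is fixed at 3 so the decision isolates the correlation
  # threshold (a rejected cluster's tail must not re-cluster as a pair)
  loose <- pick_monoisotopic(pk, preprocess_config(mono_min_cor = 0.90,
                                                   mono_size_range = c(3, 10)))
  strict <- pick_monoisotopic(pk, preprocess_config(mono_min_cor = 0.95,
                                                    mono_size_range = c(3, 10)))
  expect_equal(nrow(loose), 1)
  expect_equal(nrow(strict), 3)
})

test_that("de-isotoping never increases peak count and keeps a subset of masses", {
  set.seed(31)
  cfg <- preprocess_config()
  for (i in 1:20) {
    mz <- sort(runif(sample(3:25, 1), 1000, 3000))
    pk <- make_peaks(mz, intensity = abs(rnorm(length(mz), 5, 3)) + 0.1)
    out <- pick_monoisotopic(pk, cfg)
    expect_lte(nrow(out), nrow(pk))
    expect_true(all(out$mz %in% pk$mz))
    expect_true(!is.unsorted(out$mz))
  }
})

test_that("replicate quality control drops sparse replicates", {
  cfg <- preprocess_config()
  mk <- function(n, rep) make_peaks(seq(1000, by = 5, length.out = n),
                                    sample_id = "A") |>
    dplyr::mutate(replicate = rep, .after = "sample_id")
  pk <- dplyr::bind_rows(mk(50, 1L), mk(48, 2L), mk(2, 3L))
  out <- suppressMessages(filter_replicate_quality(pk, cfg))
  expect_equal(sort(unique(out$replicate)), c(1L, 2L))
  expect_equal(attr(out, "dropped_replicates")$replicate, 3L)

  ok <- dplyr::bind_rows(mk(10, 1L), mk(10, 2L), mk(10, 3L))
  expect_equal(nrow(filter_replicate_quality(ok, cfg)), 30)

  poor <- dplyr::bind_rows(mk(1, 1L), mk(2, 2L))
  out2 <- suppressMessages(filter_replicate_quality(poor, cfg))
  expect_equal(nrow(out2), 0)
  expect_equal(attr(out2, "failed_samples"), "A")
})

test_that("replicate averaging is the pointwise mean on a common axis", {
  a <- make_spectrum(c(1000, 1001), c(1, 3), replicate = 1L)
  b <- make_spectrum(c(1000, 1001), c(3, 5), replicate = 2L)
  avg <- average_replicates(dplyr::bind_rows(a, b))
  expect_equal(avg$intensity, c(2, 4))

  single <- make_spectrum(c(1000, 1001), c(7, 9))
  expect_equal(average_replicates(single)$intensity, c(7, 9))

  set.seed(13)
  mz <- seq(1000, 1020, by = 0.05)
  truth <- 50 + 10 * sin(mz)
  reps <- dplyr::bind_rows(lapply(1:3, function(r) {
    make_spectrum(mz, truth + rnorm(length(mz), 0, 2), replicate = r)
  }))
  avg3 <- average_replicates(reps)
  resid_sd <- sd(avg3$intensity - truth)
  expect_lt(abs(resid_sd - 2 / sqrt(3)) / (2 / sqrt(3)), 0.3)
})

test_that("the full chain recovers planted markers from triplicates", {
  eur <- fixture_eurasia()
  scfg <- synth_config(n_noise_peaks = 0, deamidation_prob = 0)
  syn <- synth_spectrum(eur, "Ursus arctos", scfg, seed = 101,
                        sample_id = "chain")
  pk <- suppressMessages(preprocess_spectra(syn$spectra))
  expect_equal(nrow(pk), nrow(syn$truth))
  deltas <- vapply(syn$truth$planted_mass, function(m) min(abs(pk$mz - m)),
                   numeric(1))
  expect_true(all(deltas <= 0.2))
  status <- attr(pk, "sample_status")
  expect_false(status$failed)

  # a single clean replicate gives the same marker set
  one_rep <- syn$spectra |> dplyr::filter(replicate == 1)
  pk1 <- suppressMessages(preprocess_spectra(one_rep))
  deltas1 <- vapply(syn$truth$planted_mass, function(m) min(abs(pk1$mz - m)),
                    numeric(1))
  expect_true(all(deltas1 <= 0.2))
})

test_that("a group of flat spectra fails quality control instead of erroring", {
  mz <- seq(1000, 1010, by = 0.02)
  flat <- dplyr::bind_rows(lapply(1:3, function(r) {
    make_spectrum(mz, rep(25, length(mz)), sample_id = "F", replicate = r)
  }))
  pk <- suppressMessages(preprocess_spectra(flat))
  expect_equal(nrow(pk), 0)
  status <- attr(pk, "sample_status")
  expect_true(status$failed[status$sample_id == "F"])
})

test_that("every stage preserves m/z ordering", {
  set.seed(77)
  mz <- seq(1000, 1030, by = 0.02)
  s <- make_spectrum(mz, abs(rnorm(length(mz), 20, 5)) +
                       60 * exp(-0.5 * ((mz - 1015) / 0.15)^2))
  for (stage in list(smooth_spectra, remove_baseline, normalize_tic)) {
    out <- stage(s)
    expect_false(is.unsorted(out$mz))
    expect_equal(nrow(out), nrow(s))
    expect_true(all(out$intensity >= 0))
    s <- out
  }
})
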