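test_that("the mass grid uses half-open bins", {
  g <- build_grid(800, 3700, 0.1)
  expect_equal(g$n_bins, 29000L)
  g2 <- build_grid(0, 1, 0.5)
  expect_equal(g2$n_bins, 2L)
  expect_equal(zoomsid:::grid_bin(g2, 0.5), 2L)  # boundary -> higher bin
  expect_equal(zoomsid:::grid_bin(g2, 0.49), 1L)
  expect_error(build_grid(800, 3700, 0), "positive")
})

test_that("reference vectorization covers the asymmetric window", {
  g <- build_grid(1570, 1590, 0.1)
  v <- vectorize_reference(1579.8, g)
  centers <- zoomsid:::grid_centers(g)
  inside <- centers >= 1579.8 - 0.3 & centers <= 1579.8 + 1.3
  expect_equal(v, as.numeric(inside))
  expect_warning(v0 <- vectorize_reference(numeric(), g), "no reference")
  expect_equal(sum(v0), 0)
})

test_that("overlapping reference windows union to a binary vector", {
  set.seed(41)
  for (i in 1:25) {
    lo <- runif(1, 800, 1000)
    g <- build_grid(lo, lo + runif(1, 5, 20), 0.1)
    masses <- sort(runif(sample(1:4, 1), g$lo, g$hi))
    v <- vectorize_reference(masses, g)
    centers <- zoomsid:::grid_centers(g)
    oracle <- vapply(centers, function(cc) {
      any(cc >= masses - 0.3 & cc <= masses + 1.3)
    }, logical(1))
    expect_equal(v, as.numeric(oracle))
    expect_true(all(v %in% c(0, 1)))
  }
})

test_that("sample vectorization marks one bin per peak and drops outliers", {
  g <- build_grid(1000, 1010, 0.1)
  v <- vectorize_sample(1004.25, g)
  expect_equal(sum(v), 1)
  expect_equal(which(v == 1), zoomsid:::grid_bin(g, 1004.25))
  expect_equal(sum(vectorize_sample(numeric(), g)), 0)
  expect_warning(v2 <- vectorize_sample(c(1004, 1100), g), "dropped")
  expect_equal(sum(v2), 1)
})

test_that("Gaussian vector smoothing preserves mass and is linear", {
  v <- numeric(101); v[51] <- 1
  expect_identical(smooth_vector(v, 0), v)
  sm <- smooth_vector(v, 2)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  expect_equal(sm[51 + 1:5], sm[51 - 1:5])  # symmetric bell
  expect_gt(sm[51], sm[50])

  a <- numeric(101); a[30] <- 1
  b <- numeric(101); b[70] <- 1
  expect_equal(smooth_vector(a + b, 2),
               smooth_vector(a, 2) + smooth_vector(b, 2), tolerance = 1e-12)
  expect_error(smooth_vector(v, -1), "non-negative")
  # spill at the edges is reflected back: mass still conserved
  e <- numeric(50); e[2] <- 1
  expect_equal(sum(smooth_vector(e, 3)), 1, tolerance = 1e-9)
})

test_that("correlation matches the textbook formula and flags degeneracy", {
  a <- c(0, 1, 1, 0, 0, 0, 1, 0)
  b <- c(0, 1, 1, 0, 0, 0, 0, 0)
  # hand-computed Pearson: cov / (sd * sd)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(correlate_vectors(a, b), oracle, ignore_attr = TRUE)
  expect_equal(correlate_vectors(a, a), 1, ignore_attr = TRUE)
  expect_message(z <- correlate_vectors(numeric(8), b), "degenerate")
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
  expect_error(correlate_vectors(a, b[1:4]), "equal length")
})

test_that("correlation is symmetric and scale invariant", {
  set.seed(9)
  for (i in 1:10) {
    a <- runif(50)
    b <- rbinom(50, 1, 0.3)
    expect_equal(correlate_vectors(a, b), correlate_vectors(b, a))
    expect_equal(suppressMessages(correlate_vectors(7.3 * a, b)),
                 suppressMessages(correlate_vectors(a, b)),
                 tolerance = 1e-12)
  }
})

test_that("marker matching honours the -0.3/+1.3 Da window", {
  markers <- tibble::tibble(marker_id = "B", mass = 1579.8)
  m <- match_markers(1580.8, markers)
  expect_equal(nrow(m), 1)
  expect_equal(m$delta, 1.0)

  expect_equal(match_markers(2000.0,
                             tibble::tibble(marker_id = "X", mass = 2000.0))$delta, 0)
  expect_equal(nrow(match_markers(2001.4,
                                  tibble::tibble(marker_id = "X", mass = 2000.0))), 0)
  expect_equal(nrow(match_markers(1999.6,
                                  tibble::tibble(marker_id = "X", mass = 2000.0))), 0)
})

test_that("marker matching is greedy one-to-one by absolute delta", {
  markers <- tibble::tibble(marker_id = c("A", "B"), mass = c(2000.0, 2001.0))
  m <- match_markers(c(2000.1, 2001.05), markers)
  expect_equal(nrow(m), 2)
  expect_equal(m$sample_mass[m$marker_id == "A"], 2000.1)
  expect_equal(m$sample_mass[m$marker_id == "B"], 2001.05)
  # one peak cannot serve two markers
  m2 <- match_markers(2000.5, markers)
  expect_equal(nrow(m2), 1)
})

test_that("contaminant scanning flags listed masses only", {
  ct <- fixture_contaminants()
  keratin <- ct$mass[ct$name == "Human keratin"][1]
  pk <- make_peaks(c(keratin + 0.1, keratin + 5))
  hits <- scan_contaminants(pk, ct)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$contaminant, "Human keratin")
  expect_equal(nrow(scan_contaminants(pk, ct[0, ])), 0)
  far <- make_peaks(ct$mass[1] + 2.0)
  expect_equal(nrow(scan_contaminants(far, ct)), 0)
})

test_that("status classification follows the marker-count rule", {
  expect_equal(classify_status(c(0, 1, 4, 5, 6, NA)),
               c("fail", "tentative", "tentative", "ok", "ok", "fail"))
})

test_that("a planted fixture species is identified at rank 1", {
  eur <- fixture_eurasia()
  markers <- eur$mass[eur$species == "Rhinoceros sp."]
  id <- identify_sample(markers + 0.05, eur, sample_id = "rhino")
  top <- id$results[id$results$rank == 1, ]
  expect_equal(top$species, "Rhinoceros sp.")
  expect_equal(top$status, "ok")
  expect_gt(top$correlation, 0)
  expect_equal(top$n_matched_markers, length(markers))
})

test_that("species with identical marker sets tie at rank 1", {
  db <- tibble::tibble(
    species = rep(c("Left sp.", "Right sp."), each = 3),
    zooms_taxon = rep(c("Left sp.", "Right sp."), each = 3),
    family = "Fam", order = "Ord",
    marker_id = rep(c("A", "B", "C"), 2),
    mass = rep(c(1200.5, 1800.5, 2400.5), 2),
    region = "Other"
  )
  id <- identify_sample(c(1200.5, 1800.5, 2400.5), db)
  r1 <- id$results[id$results$rank == 1, ]
  expect_equal(nrow(r1), 2)
  expect_equal(length(unique(r1$correlation)), 1)
  expect_setequal(r1$species, c("Left sp.", "Right sp."))
  expect_equal(unique(r1$status), "tentative")  # 3 markers only
})

test_that("adding a matching peak never lowers the species' correlation", {
  set.seed(55)
  eur <- fixture_eurasia()
  cfg <- identify_config()
  for (i in 1:10) {
    sp <- sample(unique(eur$species), 1)
    masses <- eur$mass[eur$species == sp]
    planted <- sample(masses, 4)
    extra <- setdiff(masses, planted)[1]
    decoys <- runif(5, 810, 3600)
    before <- identify_sample(c(planted, decoys), eur, cfg = cfg)
    after <- identify_sample(c(planted, extra, decoys), eur, cfg = cfg)
    corr_of <- function(x) x$results$correlation[x$results$species == sp]
    b <- corr_of(before)
    a <- corr_of(after)
    if (length(b) && length(a)) {
      expect_gte(a, b)
    }
  }
})

test_that("an empty peak list yields a fail with no candidates", {
  eur <- fixture_eurasia()
  pk <- make_peaks(numeric())
  id <- identify_taxa(pk, eur)
  expect_equal(nrow(id$results), 0)
  expect_error(identify_taxa(make_peaks(1500), eur[0, ]), "empty reference")
})

test_that("failed samples from preprocessing propagate into the results", {
  eur <- fixture_eurasia()
  pk <- make_peaks(eur$mass[eur$species == "Equus ferus"], sample_id = "good")
  attr(pk, "sample_status") <- tibble::tibble(
    sample_id = c("good", "bad"), n_replicates = 3L,
    n_replicates_kept = c(3L, 0L), n_peaks = c(nrow(pk), 0L),
    failed = c(FALSE, TRUE)
  )
  id <- identify_taxa(pk, eur)
  bad <- id$results[id$results$sample_id == "bad", ]
  expect_equal(nrow(bad), 1)
  expect_equal(bad$status, "fail")
  expect_true(is.na(bad$species))
})

test_that("batch export writes both CSV files deterministically", {
  eur <- fixture_eurasia()
  pk <- dplyr::bind_rows(
    make_peaks(eur$mass[eur$species == "Equus ferus"] + 0.02,
               sample_id = "s1"),
    make_peaks(c(eur$mass[eur$species == "Ovis aries"][1:6], 2383.95),
               sample_id = "s2")
  )
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_batch(pk, eur, contaminants = fixture_contaminants(), out_dir = d1)
  run_batch(pk, eur, contaminants = fixture_contaminants(), out_dir = d2)
  r1 <- file.path(d1, "zoomsid_results.csv")
  expect_true(file.exists(r1))
  header <- readLines(r1, n = 1)
  expect_equal(header, paste0("sample_id,rank,species,zooms_taxon,family,",
                              "order,correlation,n_matched_markers,",
                              "matched_markers,status"))
  expect_identical(unname(tools::md5sum(r1)),
                   unname(tools::md5sum(file.path(d2, "zoomsid_results.csv"))))
  cont <- readr::read_csv(file.path(d1, "zoomsid_contaminants.csv"),
                          show_col_types = FALSE)
  expect_true(any(cont$contaminant == "Human keratin" &
                    cont$sample_id == "s2"))
  expect_error(run_batch(make_peaks(numeric()), eur, out_dir = d1),
               "no samples")
})

test_that("vectorize + correlate equals a brute-force bin enumeration", {
  set.seed(66)
  cfg <- identify_config()
  for (i in 1:10) {
    lo <- runif(1, 800, 2000)
    width <- runif(1, 5, 18)
    g <- build_grid(lo, lo + width, 0.1)
    expect_lte(g$n_bins, 200)
    masses <- sort(runif(3, lo + 1, lo + width - 2))
    peaks <- sort(runif(4, lo + 0.5, lo + width - 0.5))
    centers <- zoomsid:::grid_centers(g)
    ref_oracle <- as.numeric(vapply(centers, function(cc) {
      any(cc >= masses - 0.3 & cc <= masses + 1.3)
    }, logical(1)))
    samp_oracle <- numeric(g$n_bins)
    for (p in peaks) {
      k <- which(p >= g$lo + (seq_len(g$n_bins) - 1) * g$bin_width &
                   p < g$lo + seq_len(g$n_bins) * g$bin_width)
      samp_oracle[k] <- 1
    }
    ref <- vectorize_reference(masses, g)
    samp <- vectorize_sample(peaks, g)
    expect_equal(ref, ref_oracle)
    expect_equal(samp, samp_oracle)
    sm <- smooth_vector(samp, cfg$sigma_bins)
    expect_equal(suppressMessages(as.numeric(correlate_vectors(sm, ref))),
                 suppressMessages(as.numeric(correlate_vectors(ref, sm))))
  }
})
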