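---
title: "Methods: automated taxonomic identification of collagen fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated taxonomic identification of collagen fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Zooarchaeology by Mass Spectrometry (ZooMS) identifies the taxon of a bone
fragment from the masses of its tryptic collagen peptides. A MALDI-ToF
spectrum of digested bone collagen contains a handful of taxon-diagnostic
"peptide marker" peaks (conventionally lettered A-G, P1, P2); matching the
observed marker masses against a reference table of species' marker masses
yields the finest taxonomic group the markers can resolve — the *ZooMS
taxon*, which is often compound (e.g. "Cervus/Saiga/Gazella") because close
relatives share collagen sequences. `zoomsid` automates the whole chain:
raw spectra in, ranked candidate taxa with correlation scores,
matched markers, contaminant flags and a fail status out.

This vignette documents the model and the choices behind each stage:
what is computed, which parameters matter, and what the synthetic
validation does and does not demonstrate.

# Preprocessing raw replicates

Samples are spotted in technical triplicate; each replicate is a continuous
(m/z, intensity) profile. Per replicate the chain is:

1. **Savitzky-Golay smoothing** (`smooth_spectra()`): local least-squares
   polynomial fit, default half-window 10 points, order 3. The window is
   deliberately small relative to isotopic spacing (~1 Da) so adjacent
   isotope peaks are never merged; negative fitted values are clamped to 0.
2. **SNIP baseline removal** (`remove_baseline()`): iterative peak
   clipping with a *decreasing* window, default 100 iterations (= largest
   clipping half-window in points). The decreasing schedule avoids the
   stepped artefacts of the increasing variant on narrow MALDI peaks. The
   clipped estimate is subtracted and negatives are clamped to 0, so peak
   apex heights above the local baseline are preserved.
3. **Total-ion-current calibration** (`normalize_tic()`): intensities are
   divided by their sum. Every spectrum then carries unit total ion
   current, making replicates and samples comparable; the sum is 1 to
   within 1e-12 by construction.
4. **Noise estimation** (`estimate_noise()`): the local noise *scale* is
   the distance from the chunk median to the chunk 84th percentile,
   interpolated across the spectrum (about 50 equal chunks). For Gaussian
   noise this equals one standard deviation, and it remains a 1-sigma
   estimate after negatives have been clamped to zero, where the usual MAD
   collapses. Quantiles above the 84th are the only ones sparse peaks can
   reach, so the estimator is robust to real signal. The chunk *median*
   itself is kept as the local noise-band center.
5. **Peak detection** (`detect_peaks()`): strict local maxima within a
   ±20-point window whose excess over the local noise-band center is at
   least `snr_threshold` times the local noise scale. Apexes whose window
   is truncated by the spectrum ends are discarded.
6. **De-isotoping** (`pick_monoisotopic()`): peaks spaced 1.00235 Da apart
   (relative tolerance 1e-4) are chained into isotopic clusters of size
   2-10. A cluster collapses to its lowest-mass member only when its
   intensity pattern correlates at least `mono_min_cor` (default 0.95)
   with a modelled isotopic pattern; lowering the threshold (0.94-0.90) is
   useful for noisy or deamidated data. The model is the
   Poisson-approximated averagine distribution with mean linear in mass
   (`0.000594 m − 0.031`), so low-mass envelopes decay and envelopes above
   ~1800 Da peak on a satellite rather than the monoisotopic peak —
   which is why apex height alone cannot identify the monoisotopic peak.

Replicates whose de-isotoped peak count falls below 5, or below half the
sample's median replicate peak count, are dropped (the source method
describes this quality control as visual histogram inspection; the
two-threshold rule is our operationalization). Surviving preprocessed
*profiles* are linearly interpolated onto the union m/z grid and averaged
pointwise, which suppresses uncorrelated noise by roughly the square root
of the replicate count; peak picking and de-isotoping are then repeated on
the averaged spectrum to give the sample's final peak list. Averaging
profiles and re-picking (rather than merging peak lists) keeps peaks that
are individually near-threshold in each replicate but consistent across
them.

## Why the default SNR threshold is 6

The conventional manual-analysis setting "SNR = 3" refers to a visual
noise *band*; our noise level is pinned to 1 sigma by the estimator above.
A collagen fingerprint profile holds on the order of 1e5 points, i.e.
thousands of effectively independent local maxima of smoothed noise, whose
expected maximum is near 3.7 sigma — a 3-sigma cut would therefore pass
dozens of pure-noise peaks per spectrum. At 6 sigma the expected number of
false peaks per spectrum is far below one, while planted peaks at the
generator's weakest setting (30 × noise) remain detectable with a wide
margin even after smoothing attenuation. The threshold is a config field
(`preprocess_config(snr_threshold = ...)`), not a constant.

# Identification by correlation

The sample's peak list and a *geographically partitioned* reference table
are compared on a discretized mass axis (default 800-3700 Da, 0.1 Da
bins, half-open `[lo + kw, lo + (k+1)w)`):

* **Reference side**: for each species, a binary vector with ones in every
  bin whose center lies within **−0.3 to +1.3 Da** of one of the species'
  marker masses. The asymmetric window combines the ±0.3 Da instrument
  accuracy with the ≈+1 Da mass shift that glutamine/asparagine
  deamidation adds; it is applied to all markers uniformly because
  deamidated and unmodified peptides convolve in degraded samples.
* **Sample side**: a binary indicator (one per bin containing a detected
  peak) convolved with a discrete Gaussian (default sigma 2 bins; mass
  spilling past the vector ends is reflected back so the total is exactly
  conserved). The smoothing lets a peak near a window edge still
  contribute partial weight.
* **Score**: the Pearson correlation of the two vectors. A constant
  vector scores 0 and is flagged degenerate. Scores are relative — they
  depend on collagen preservation, marker availability and species
  similarity — so the package ranks candidates rather than applying a
  universal score threshold.

Candidates are ranked by correlation; ties share a rank and are all
reported (beyond `n_top = 3` if necessary), because tied species are
genuinely indistinguishable on the data — disambiguation by geography or
period is the analyst's call. Marker matching (for reporting, not
scoring) uses exact mass arithmetic in the same −0.3/+1.3 Da window with
greedy one-to-one assignment by smallest absolute delta, so a single peak
never counts for two markers of one species.

**Status**: a sample is `fail` with no candidates or zero matched
markers, `tentative` when the top candidate rests on 1-4 distinct
markers (such identifications warrant manual inspection), and `ok` from 5
markers. "Distinct" counts marker identifiers, not peaks.

Contaminant scanning compares every detected peak against a user-supplied
list of known contaminant masses (keratins, trypsin autolysis, matrix
clusters, casein, serum albumin) in the same window; hits are reported
alongside the identification so flagged peaks can be discounted.

Region partitioning is essential rather than cosmetic: Eurasian and
African relatives share markers, and a pooled database yields
geographically impossible candidates. The packaged fixture encodes
region as a column; per-region files with the same schema work equally.

# Evaluation against manual labels

`evaluate_identifications()` joins rank-1 calls to a manual-label table.
Pairs where either side is a fail are excluded before any statistic,
since the ranker always produces *some* closest match even from one or
two peaks. Labels are compared as compound atoms: both sides are
case-folded, "sp." suffixes and punctuation stripped, split on "/", and
a prediction matches the manual label when the atom sets intersect
("Cervus/Saiga/Gazella/Rangifer" vs "Cervus/Saiga/Gazella" is a match —
the algorithm was not wrong, the data cannot separate them). Per-site
accuracies are pooled as the sample-size weighted mean `Σ nᵢaᵢ / Σ nᵢ`.
Confusion matrices are tallied at taxon level; correlation scores of true
and false calls are compared with a Welch two-sample t-test
(pooled-variance Student form available via `var_equal = TRUE`).

# The synthetic-spectrum generator

`synth_spectrum()` renders profile spectra with known ground truth; it is
the package's validation instrument. The default configuration is fixed
and describes a well-behaved collagen fingerprint:

| parameter | default | meaning |
|---|---|---|
| axis | 800-3700 Da, 0.02 Da/point | typical fingerprint range, profile sampling |
| replicates | 3 | triplicate spotting |
| resolving power | 10 000 | Gaussian peaks, FWHM = m/R |
| marker height | 30-100 × noise | well-preserved collagen |
| noise | sd 1 (white) | detector noise |
| baseline | 20 × exp(−(m−800)/800) | decaying chemical background |
| decoy peaks | 30 per sample, 2-40 × noise | unassigned/junk peptide peaks |
| deamidation | p = 0.2, +0.984016 Da | per-marker stochastic shift |
| mass error | sd 0.05 Da (sample) + 0.01 Da (replicate) | calibration and spotting |
| satellites | Poisson-averagine, 3 | isotopic envelopes |

Decoy peaks are drawn once per sample and rendered in every replicate
(chemical noise belongs to the digest, not the spot), with per-replicate
±20% height variation like real spot-to-spot variability. Contaminant
peaks (e.g. human keratin) can be planted from the same list the scanner
uses.

What the generator does **not** emulate: ionization suppression,
mass-dependent intensity bias, detector saturation, Poisson counting
statistics, peak-shape asymmetry, calibration drift across the mass
range, and PTMs beyond deamidation. Passing the synthetic validation
therefore demonstrates that the pipeline's logic is correct under
realistic geometry and noise — not that any particular accuracy will be
attained on real archaeological material, where preservation and
database resolution dominate.

Validation properties (all in the test suite, seeded):

* with ≥5 planted markers, decoys, and a keratin contaminant, rank-1
  species recovery across 200 samples is ≥95% (the observed rate is
  typically ~99%);
* with ≤4 planted markers no sample is ever called `ok`;
* at zero noise the planted marker set is recovered exactly;
* vectorization plus correlation agrees with a brute-force
  bin-enumeration oracle on small grids;
* batch outputs are byte-identical across reruns with a fixed seed.

The problem sizes (200 samples for recovery, 100 oracle fixtures, 30
few-marker samples) were chosen to hold the relevant proportions'
sampling error near or below one percentage point while keeping the
default test run to a few minutes.

# Numerical and degenerate-input choices

* Unsorted m/z axes are sorted (with a warning) rather than rejected;
  duplicate m/z points keep the maximum intensity.
* A replicate left with zero total intensity after baseline removal
  cannot be TIC-calibrated and is dropped into the quality-control path
  (the sample fails if no replicate survives) instead of aborting a
  batch.
* A mass exactly on a bin boundary belongs to the higher bin (half-open
  bins); marker matching uses exact mass arithmetic precisely so that
  bin-boundary artefacts cannot flip a match decision.
* Zero-variance vectors correlate to 0 with a degenerate flag rather
  than propagating `NA`.
* Two-point isotopic clusters have a degenerate ±1 Pearson correlation
  with any model; they collapse only when the observed direction matches
  the modelled one.
* All randomness is seed-derived; `synth_dataset()` derives one
  sub-seed per sample from the master seed, so datasets are
  bitwise-reproducible and individual samples can be regenerated.

# Known limitations

* Correlation scores are not calibrated probabilities; no universal
  decision threshold exists across sites, and none is offered.
* The de-isotoping model shares its Poisson-averagine form with the
  generator's envelopes; agreement there is a consistency check, not an
  independent validation of the averagine approximation itself.
* The packaged reference table and contaminant list are synthetic
  fixtures with realistic structure (shared bovid markers, the
  Mustela/Phocid marker overlap, a six-marker African elephant), intended
  for tests and examples; real analyses should drop in a curated marker
  database with the same schema.
* Charge state +1 is assumed throughout; no vendor binary formats.
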