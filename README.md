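# zoomsid

Automated taxonomic identification of bone-collagen peptide mass
fingerprints (ZooMS) from raw MALDI-ToF spectra.

## The problem

ZooMS identifies the taxon of (often morphologically undiagnostic) bone
by the masses of its tryptic collagen peptides. A handful of
taxon-diagnostic *peptide markers* (COL1α1/α2 peptides, conventionally
lettered A–G, P1, P2) act as a barcode: matching observed marker masses
against a reference table of species' marker masses yields the finest
group the markers resolve — the **ZooMS taxon**, which may be compound
("Cervus/Saiga/Gazella") where close relatives share collagen sequences.
Manual spectrum reading is slow, order-dependent and hard to reproduce;
`zoomsid` automates it for high-throughput screening, producing ranked
candidates with correlation scores instead of a single unquantified call.

## The method

For each sample, technical replicate profiles are smoothed
(Savitzky–Golay), baseline-corrected (SNIP iterative peak clipping),
TIC-calibrated, peak-picked against a robust local noise estimate, and
de-isotoped (Poisson-averagine isotopic-pattern correlation,
`minCor = 0.95`). Low-quality replicates are dropped, survivors averaged,
and picking repeated on the average. Identification then discretizes the
mass axis (800–3700 Da, 0.1 Da bins) and scores every species *s* of a
geographically partitioned reference database by Pearson correlation

    r_s = cor( G_sigma * x ,  w_s )

where `x` is the binary indicator of detected peak bins, `G_sigma *x` its
Gaussian smoothing (sigma = 2 bins), and `w_s` the binary union of windows
`[m − 0.3, m + 1.3]` Da over the species' marker masses `m` (±0.3 Da
instrument accuracy, +1 Da maximal deamidation shift). Candidates are
ranked by `r_s` (ties share a rank and are all reported); markers are
matched one-to-one within the same window; peaks are scanned against a
known-contaminant list; samples with ≤4 matched markers are flagged
`tentative`, with none `fail`. An evaluation module compares calls with
manual labels via compound-label matching, confusion matrices,
sample-size-weighted accuracies and Welch t-tests on correlation scores.

## Worked example

A degraded African sample yielded six de-isotoped peaks. Identifying them
against the packaged (synthetic-fixture) African reference partition:

```r
library(zoomsid)

db     <- read_reference_db(zoomsid_example("zooms_markers_synthetic.csv"))
africa <- partition_by_region(db, "Africa")
contam <- read_contaminants(zoomsid_example("contaminants_synthetic.csv"))

peaks <- c(1105.6, 1453.7, 1579.8, 2115.1, 2808.4, 2853.4)
id <- identify_sample(peaks, africa, contaminants = contam, sample_id = "KAV458")
tidy(id)
#> # A tibble: 3 × 9
#>   sample_id species zooms_taxon family order correlation  rank n_matched_markers
#>   <chr>     <chr>   <chr>       <chr>  <chr>       <dbl> <int>             <int>
#> 1 KAV458    Loxodo… Loxodonta … Eleph… Prob…      0.618      1                 6
#> 2 KAV458    Syncer… Syncerus s… Bovid… Arti…      0.0975     2                 1
#> 3 KAV458    Giraff… Giraffa sp. Giraf… Arti…      0.0975     3                 1
```

All six peaks fall inside windows of *Loxodonta* markers
(`n_matched_markers = 6`, so the call is `ok`), and its correlation
(0.618) dwarfs the next candidates, which each catch only the shared
P1 mass 1105.6. The tie at rank 2/3 is reported as such. Starting from
raw spectra instead:

```r
spectra <- read_spectra(Sys.glob("spectra/*.txt")) |> group_replicates()
peaks   <- preprocess_spectra(spectra)             # full per-replicate chain
result  <- identify_taxa(peaks, africa, contaminants = contam)
write_results(result, "results")                   # results + contaminants CSVs
```

A command-line front-end (`inst/cli/zoomsid`) wraps the same functions:
`zoomsid preprocess|identify|evaluate|synth ...`, writing a resolved-config
manifest next to every output.

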