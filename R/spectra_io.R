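# Reading and writing raw spectra and peak lists.
#
# Spectra live in long tibbles with columns sample_id, replicate, mz,
# intensity; all downstream stages take and return this shape so calls
# chain with the pipe.

#' Read spectra from an mzML file
#'
#' Reads every spectrum in an mzML file into a long tibble. The m/z axis of
#' each spectrum is sorted ascending (with a warning) if the file stores it
#' unsorted; duplicate m/z values keep the maximum intensity. A singly
#' charged (MALDI) assumption is made throughout: m/z values are treated as
#' masses in Da.
#'
#' @param path Path to an mzML file.
#' @param sample_id Sample identifier to assign; defaults to the file name
#'   without extension.
#' @return A tibble with columns `sample_id`, `replicate`, `mz`,
#'   `intensity`; one `replicate` per spectrum element in the file.
#' @export
read_mzml <- function(path, sample_id = NULL) {
  if (!file.exists(path)) {
    stop("mzML file not found: ", path, call. = FALSE)
  }
  handle <- tryCatch(
    mzR::openMSfile(path),
    error = function(e) {
      stop("cannot read '", path, "' as mzML: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  on.exit(mzR::close(handle))
  n <- length(handle)
  if (n < 1) {
    stop("mzML file '", path, "' contains no spectra", call. = FALSE)
  }
  sample_id <- sample_id %||% tools::file_path_sans_ext(basename(path))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    xy <- mzR::peaks(handle, i)
    s <- sort_spectrum_xy(xy[, 1], xy[, 2], warn_source = paste0(path, " [", i, "]"))
    out[[i]] <- tibble(
      sample_id = sample_id,
      replicate = i,
      mz = s$mz,
      intensity = s$intensity,
      source_path = path
    )
  }
  dplyr::bind_rows(out)
}

#' Read a spectrum from two-column delimited text
#'
#' Parses a plain-text spectrum of m/z and intensity columns. Lines starting
#' with `#` and blank lines are skipped. Descending input is sorted
#' ascending with a warning.
#'
#' @param path Path to the text file.
#' @param delim Column delimiter; `NULL` (default) splits on any run of
#'   whitespace, commas, or semicolons.
#' @param sample_id,replicate Identity assigned to the spectrum; `sample_id`
#'   defaults to the file name without extension.
#' @return A one-spectrum tibble (`sample_id`, `replicate`, `mz`,
#'   `intensity`).
#' @export
read_xy_text <- function(path, delim = NULL, sample_id = NULL, replicate = 1L) {
  if (!file.exists(path)) {
    stop("spectrum file not found: ", path, call. = FALSE)
  }
  lines <- readr::read_lines(path)
  data_row <- !grepl("^\\s*(#|$)", lines)
  if (!any(data_row)) {
    stop("no data rows in '", path, "'", call. = FALSE)
  }
  line_no <- which(data_row)
  split_re <- if (is.null(delim)) "[\\s,;]+" else stringr::fixed(delim)
  parts <- stringr::str_split(trimws(lines[data_row]), split_re)
  bad_shape <- lengths(parts) < 2
  if (any(bad_shape)) {
    stop("line ", line_no[which(bad_shape)[1]], " of '", path,
         "' does not have two columns", call. = FALSE)
  }
  mz <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  intensity <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- is.na(mz) | is.na(intensity)
  if (any(bad)) {
    stop("non-numeric value on line ", line_no[which(bad)[1]], " of '", path,
         "'", call. = FALSE)
  }
  s <- sort_spectrum_xy(mz, intensity, warn_source = path)
  tibble(
    sample_id = sample_id %||% tools::file_path_sans_ext(basename(path)),
    replicate = as.integer(replicate),
    mz = s$mz,
    intensity = s$intensity,
    source_path = path
  )
}

#' Read a batch of spectrum files
#'
#' Convenience wrapper dispatching on file extension (`.mzML` vs text) and
#' stacking the results. Sample identity comes from file names; pass the
#' result to [group_replicates()] to recover technical-replicate structure.
#'
#' @param paths Character vector of file paths.
#' @param delim Delimiter for text files (see [read_xy_text()]).
#' @return A long spectra tibble.
#' @export
read_spectra <- function(paths, delim = NULL) {
  if (!length(paths)) {
    stop("no spectrum files given", call. = FALSE)
  }
  purrr::map(paths, function(p) {
    if (grepl("\\.mzml$", p, ignore.case = TRUE)) {
      read_mzml(p)
    } else {
      read_xy_text(p, delim = delim)
    }
  }) |>
    dplyr::bind_rows()
}

#' Group spectra into technical replicates
#'
#' MALDI samples are typically spotted in triplicate; each spot yields one
#' spectrum whose file name encodes the sample and replicate, e.g.
#' `bone12_1`, `bone12_2`, `bone12_3`. This function rewrites `sample_id`
#' and `replicate` from a regular expression with two capture groups
#' (sample, replicate index). Spectra whose id does not match the pattern
#' keep their current identity.
#'
#' @param spectra A spectra tibble (see [read_spectra()]).
#' @param id_pattern Regular expression with exactly two capture groups; the
#'   default takes a trailing `_<digits>` (or `-<digits>`) suffix as the
#'   replicate index.
#' @return The spectra tibble with `sample_id`/`replicate` rewritten; every
#'   input spectrum appears in exactly one group.
#' @export
group_replicates <- function(spectra, id_pattern = "^(.*)[_-](\\d+)$") {
  check_spectra(spectra)
  ids <- spectra |>
    dplyr::distinct(.data$sample_id, .data$replicate)
  m <- stringr::str_match(ids$sample_id, id_pattern)
  if (ncol(m) != 3) {
    stop("`id_pattern` must contain exactly two capture groups ",
         "(sample id, replicate index)", call. = FALSE)
  }
  hit <- !is.na(m[, 1])
  if (!any(hit)) {
    stop("`id_pattern` matched none of the sample ids", call. = FALSE)
  }
  ids$new_sample <- ifelse(hit, m[, 2], ids$sample_id)
  ids$new_replicate <- ifelse(hit, suppressWarnings(as.integer(m[, 3])),
                              ids$replicate)
  out <- spectra |>
    dplyr::inner_join(ids, by = c("sample_id", "replicate")) |>
    dplyr::mutate(
      sample_id = .data$new_sample,
      replicate = as.integer(.data$new_replicate)
    ) |>
    dplyr::select(-"new_sample", -"new_replicate")
  sizes <- out |>
    dplyr::distinct(.data$sample_id, .data$replicate) |>
    dplyr::count(.data$sample_id)
  singletons <- sizes$sample_id[sizes$n == 1]
  if (length(singletons)) {
    warning("sample(s) with a single replicate: ",
            paste(singletons, collapse = ", "), call. = FALSE)
  }
  out
}

#' Write and read peak lists as CSV
#'
#' Peak lists use the schema `sample_id,mz,intensity,snr` so that
#' preprocessed peaks can round-trip through plain files between pipeline
#' stages.
#'
#' @param peaks A peaks tibble with at least those columns.
#' @param path Output (or input) CSV path.
#' @return `write_peaks()` returns `path` invisibly; `read_peaks()` returns
#'   a peaks tibble.
#' @export
write_peaks <- function(peaks, path) {
  needed <- c("sample_id", "mz", "intensity", "snr")
  missing <- setdiff(needed, names(peaks))
  if (length(missing)) {
    stop("peaks are missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(peaks[needed], path)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           sample_id = readr::col_character(),
                           mz = readr::col_double(),
                           intensity = readr::col_double(),
                           snr = readr::col_double()
                         ))
  as_tibble(out)
}

#' Write spectra to two-column text files
#'
#' One file per (sample, replicate), named `<sample_id>_<replicate>.txt`,
#' containing whitespace-separated m/z and intensity columns.
#'
#' @param spectra A spectra tibble.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_xy_text <- function(spectra, dir) {
  check_spectra(spectra)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  groups <- spectra |>
    dplyr::group_by(.data$sample_id, .data$replicate) |>
    dplyr::group_split()
  paths <- vapply(groups, function(g) {
    p <- file.path(dir, sprintf("%s_%d.txt", g$sample_id[1], g$replicate[1]))
    readr::write_lines(sprintf("%.6f %.8g", g$mz, g$intensity), p)
    p
  }, character(1))
  invisible(paths)
}

#' Write spectra to a minimal mzML file
#'
#' Emits an uncompressed, 64-bit mzML 1.1.0 document with one `<spectrum>`
#' element per (sample, replicate). Intended for interchange of synthetic or
#' preprocessed spectra; instrument metadata is not carried.
#'
#' @param spectra A spectra tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path) {
  check_spectra(spectra)
  groups <- spectra |>
    dplyr::group_by(.data$sample_id, .data$replicate) |>
    dplyr::group_split()
  enc <- function(x) {
    base64enc::base64encode(writeBin(as.double(x), raw(), size = 8,
                                     endian = "little"))
  }
  spec_xml <- purrr::imap_chr(groups, function(g, i) {
    bmz <- enc(g$mz)
    bint <- enc(g$intensity)
    paste0(
      '      <spectrum index="', i - 1L, '" id="sample=', g$sample_id[1],
      ' replicate=', g$replicate[1], '" defaultArrayLength="', nrow(g), '">\n',
      '        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>\n',
      '        <cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum" value=""/>\n',
      '        <binaryDataArrayList count="2">\n',
      '          <binaryDataArray encodedLength="', nchar(bmz), '">\n',
      '            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
      '            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
      '            <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n',
      '            <binary>', bmz, '</binary>\n',
      '          </binaryDataArray>\n',
      '          <binaryDataArray encodedLength="', nchar(bint), '">\n',
      '            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
      '            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
      '            <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>\n',
      '            <binary>', bint, '</binary>\n',
      '          </binaryDataArray>\n',
      '        </binaryDataArrayList>\n',
      '      </spectrum>\n'
    )
  })
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '  <cvList count="1">\n',
    '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>\n',
    '  </cvList>\n',
    '  <fileDescription>\n',
    '    <fileContent>\n',
    '      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>\n',
    '    </fileContent>\n',
    '  </fileDescription>\n',
    '  <softwareList count="1"><software id="zoomsid" version="0.1"/></softwareList>\n',
    '  <instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>\n',
    '  <dataProcessingList count="1"><dataProcessing id="DP1"><processingMethod order="1" softwareRef="zoomsid"/></dataProcessing></dataProcessingList>\n',
    '  <run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    '    <spectrumList count="', length(groups), '" defaultDataProcessingRef="DP1">\n',
    paste0(spec_xml, collapse = ""),
    '    </spectrumList>\n',
    '  </run>\n',
    '</mzML>\n'
  )
  writeLines(doc, path, sep = "")
  invisible(path)
}
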