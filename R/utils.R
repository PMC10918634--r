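# Internal helpers shared across modules.

# Columns every spectra tibble must carry. Spectra are stored long:
# one row per (sample_id, replicate, mz) point.
.spectra_cols <- c("sample_id", "replicate", "mz", "intensity")

check_spectra <- function(spectra, arg = "spectra") {
  if (!is.data.frame(spectra)) {
    stop("`", arg, "` must be a data frame of spectra", call. = FALSE)
  }
  missing <- setdiff(.spectra_cols, names(spectra))
  if (length(missing)) {
    stop("`", arg, "` is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(spectra$intensity < 0, na.rm = TRUE)) {
    stop("`", arg, "` contains negative intensities", call. = FALSE)
  }
  invisible(spectra)
}

# Apply `f(tbl, ...)` to each (sample_id, replicate) sub-spectrum; `f` gets
# and returns a tibble without the key columns.
per_spectrum <- function(spectra, f, ...) {
  spectra |>
    dplyr::group_by(.data$sample_id, .data$replicate) |>
    dplyr::group_modify(function(d, key) f(d, ...)) |>
    dplyr::ungroup()
}

# Sort one spectrum by mz, collapsing duplicate mz values to the maximum
# intensity (real exports occasionally repeat grid points).
sort_spectrum_xy <- function(mz, intensity, warn_source = NULL) {
  if (is.unsorted(mz, strictly = TRUE)) {
    if (!is.null(warn_source)) {
      warning("m/z values in ", warn_source,
              " were not strictly ascending; sorting", call. = FALSE)
    }
    o <- order(mz, -intensity)
    mz <- mz[o]
    intensity <- intensity[o]
    keep <- !duplicated(mz)
    mz <- mz[keep]
    intensity <- intensity[keep]
  }
  list(mz = mz, intensity = intensity)
}

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}
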