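# Peptide-marker reference databases and contaminant lists.
#
# A reference table has one row per (species, marker, mass) with the
# species -> ZooMS taxon -> family -> order lineage and a geographic region
# label; identification is always run against a single region's partition.

.region_levels <- c("Eurasia", "Africa", "NewWorld", "Other")

normalize_region <- function(x) {
  key <- tolower(gsub("[^a-z]", "", tolower(x)))
  out <- unname(c(eurasia = "Eurasia", africa = "Africa",
                  newworld = "NewWorld", other = "Other")[key])
  ifelse(is.na(out), as.character(unname(x)), out)
}

# numeric scalar or a ";"/"/"-separated list of numerics
.mass_cell_re <- "^\\s*[0-9]+(\\.[0-9]+)?(\\s*[;/]\\s*[0-9]+(\\.[0-9]+)?)*\\s*$"

#' Load a peptide-marker reference table
#'
#' Reads a delimited reference table with (at least) columns `species`,
#' `marker_id`, `mass`; columns `zooms_taxon`, `family`, `order` and
#' `region` are carried when present and filled with defaults otherwise.
#' Mass cells may hold several `;`- or `/`-separated values (one marker
#' with multiple reported masses); [clean_reference_db()] splits them into
#' one row each.
#'
#' @param path Path to the CSV file.
#' @param clean Apply [clean_reference_db()] before returning (default).
#' @param taxon_map Optional named character vector mapping species to
#'   ZooMS taxon labels, passed to [clean_reference_db()].
#' @return A tibble of marker records (mass numeric after cleaning).
#' @export
read_reference_db <- function(path, clean = TRUE, taxon_map = NULL) {
  if (!file.exists(path)) {
    stop("reference database file not found: ", path, call. = FALSE)
  }
  db <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  required <- c("species", "marker_id", "mass")
  missing <- setdiff(required, names(db))
  if (length(missing)) {
    stop("reference database '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(!grepl(.mass_cell_re, db$mass))
  if (length(bad)) {
    stop("non-numeric mass in reference database row(s) ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "", call. = FALSE)
  }
  for (col in c("zooms_taxon", "family", "order", "region")) {
    if (!col %in% names(db)) db[[col]] <- NA_character_
  }
  db <- as_tibble(db[c("species", "zooms_taxon", "family", "order",
                       "marker_id", "mass", "region")])
  if (clean) clean_reference_db(db, taxon_map = taxon_map) else db
}

#' Clean a reference table
#'
#' Normalizes whitespace and stray punctuation in text fields, splits mass
#' cells holding several `;`- or `/`-separated values into one record per
#' mass, fills `zooms_taxon` (from `taxon_map`, defaulting to the species
#' name), canonicalizes region labels, removes duplicate (species,
#' marker_id, mass) records and drops markers outside the 800-4000 Da
#' fingerprinting range with a warning. The operation is idempotent.
#'
#' @param db A reference tibble from [read_reference_db()] (mass may be
#'   character or numeric).
#' @param taxon_map Optional named character vector, `species -> taxon`.
#' @return A cleaned tibble with numeric `mass`.
#' @export
clean_reference_db <- function(db, taxon_map = NULL) {
  squish <- function(x) {
    x <- stringr::str_squish(as.character(x))
    x <- stringr::str_remove_all(x, "[\"']")
    x[x %in% c("", "NA")] <- NA_character_
    x
  }
  for (col in c("species", "zooms_taxon", "family", "order", "marker_id",
                "region")) {
    if (col %in% names(db)) db[[col]] <- squish(db[[col]])
  }
  db <- db |>
    dplyr::filter(!is.na(.data$species))
  if (is.character(db$mass)) {
    db <- db |>
      tidyr::separate_rows("mass", sep = "\\s*[;/]\\s*")
  }
  db$mass <- as.numeric(db$mass)
  if (anyNA(db$mass)) {
    stop("reference database contains unparseable mass values", call. = FALSE)
  }
  out_of_range <- !is.na(db$mass) & (db$mass < 800 | db$mass > 4000)
  if (any(out_of_range)) {
    warning(sum(out_of_range), " marker(s) outside the 800-4000 Da range ",
            "were dropped", call. = FALSE)
    db <- db[!out_of_range, ]
  }
  fill <- is.na(db$zooms_taxon)
  if (!is.null(taxon_map)) {
    mapped <- unname(taxon_map[db$species])
    db$zooms_taxon[fill] <- mapped[fill]
    fill <- is.na(db$zooms_taxon)
  }
  db$zooms_taxon[fill] <- db$species[fill]
  db$region <- ifelse(is.na(db$region), "Other", normalize_region(db$region))
  db |>
    dplyr::distinct(.data$species, .data$marker_id, .data$mass,
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$species, .data$mass)
}

#' Partition a reference table by geographic region
#'
#' Species identification is run against a single geographic partition of
#' the reference table, because related taxa on different continents often
#' share peptide markers and would otherwise produce geographically
#' impossible candidates.
#'
#' @param db A cleaned reference tibble.
#' @param region One of `"Eurasia"`, `"Africa"`, `"NewWorld"`, `"Other"`
#'   (case and punctuation insensitive).
#' @return The subset of `db` for that region, with a `region_label`
#'   attribute.
#' @export
partition_by_region <- function(db, region) {
  region <- normalize_region(region)
  if (length(region) != 1 || !region %in% .region_levels) {
    stop("unknown region '", region, "'; valid regions are: ",
         paste(.region_levels, collapse = ", "), call. = FALSE)
  }
  out <- db |> dplyr::filter(normalize_region(.data$region) == !!region)
  if (!nrow(out)) {
    warning("no reference records for region '", region, "'", call. = FALSE)
  }
  attr(out, "region_label") <- region
  out
}

#' Load a contaminant mass list
#'
#' Reads a two-column `name,mass` CSV of known contaminant peptide masses
#' (keratins, trypsin autolysis products, matrix clusters, casein, serum
#' albumin, ...). The same protein may contribute many rows.
#'
#' @param path Path to the CSV.
#' @return A tibble `name`, `mass`.
#' @export
read_contaminants <- function(path) {
  if (!file.exists(path)) {
    stop("contaminant file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!nrow(raw)) {
    warning("contaminant list '", path, "' is empty", call. = FALSE)
    return(tibble(name = character(), mass = numeric()))
  }
  missing <- setdiff(c("name", "mass"), names(raw))
  if (length(missing)) {
    stop("contaminant list '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mass <- suppressWarnings(as.numeric(raw$mass))
  bad <- which(is.na(mass))
  if (length(bad)) {
    stop("non-numeric mass in contaminant list row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  tibble(name = stringr::str_squish(raw$name), mass = mass)
}
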