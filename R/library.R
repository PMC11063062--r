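# SQLite reference spectral libraries. Fixed schema:
#   spectra(record_id INTEGER PRIMARY KEY, compound_name TEXT, formula TEXT,
#           inchikey TEXT, precursor_mz REAL, adduct TEXT, polarity TEXT,
#           collision_energy TEXT, instrument_type TEXT, peaks_mz TEXT,
#           peaks_intensity TEXT, fragment_formulas TEXT)
#   meta(key TEXT, value TEXT)  -- holds schema_version
# Peak arrays are semicolon-joined decimal strings.

LIBRARY_SCHEMA_VERSION <- "1.0"

#' Open an SQLite reference spectra library
#'
#' @param path SQLite file following the library schema.
#' @return a library handle of class `ms2_library`; close with
#'   [close_library()].
#' @export
open_library <- function(path) {
  if (!file.exists(path)) stop("library not found: ", path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  tabs <- DBI::dbListTables(con)
  if (!all(c("spectra", "meta") %in% tabs)) {
    DBI::dbDisconnect(con)
    stop("schema mismatch: library must contain tables 'spectra' and 'meta'")
  }
  ver <- DBI::dbGetQuery(con, "SELECT value FROM meta WHERE key='schema_version'")
  if (!nrow(ver) || ver$value[1] != LIBRARY_SCHEMA_VERSION) {
    DBI::dbDisconnect(con)
    stop("schema version mismatch: expected ", LIBRARY_SCHEMA_VERSION,
         ", found ", if (nrow(ver)) ver$value[1] else "none")
  }
  cols <- DBI::dbListFields(con, "spectra")
  need <- c("record_id", "compound_name", "formula", "inchikey",
            "precursor_mz", "adduct", "polarity", "collision_energy",
            "instrument_type", "peaks_mz", "peaks_intensity",
            "fragment_formulas")
  if (!all(need %in% cols)) {
    DBI::dbDisconnect(con)
    stop("schema mismatch: missing columns ",
         paste(setdiff(need, cols), collapse = ", "))
  }
  structure(list(con = con, path = path), class = "ms2_library")
}

#' @export
print.ms2_library <- function(x, ...) {
  n <- DBI::dbGetQuery(x$con, "SELECT COUNT(*) AS n FROM spectra")$n
  cat(sprintf("<ms2_library> %s (%d records)\n", x$path, n))
  invisible(x)
}

#' @rdname open_library
#' @param library an `ms2_library` handle.
#' @export
close_library <- function(library) {
  DBI::dbDisconnect(library$con)
  invisible(NULL)
}

row_to_record <- function(r) {
  mz <- as.numeric(strsplit(r$peaks_mz, ";", fixed = TRUE)[[1]])
  ii <- as.numeric(strsplit(r$peaks_intensity, ";", fixed = TRUE)[[1]])
  ff <- if (!is.na(r$fragment_formulas) && nzchar(r$fragment_formulas)) {
    f <- strsplit(r$fragment_formulas, ";", fixed = TRUE)[[1]]
    f[f == ""] <- NA_character_
    f
  } else NULL
  structure(list(
    record_id = r$record_id, compound_name = r$compound_name,
    formula = r$formula, inchikey = r$inchikey,
    precursor_mz = r$precursor_mz, adduct = r$adduct, polarity = r$polarity,
    collision_energy = r$collision_energy,
    instrument_type = r$instrument_type,
    spectrum = spectrum(mz, ii, precursor_mz = r$precursor_mz,
                        polarity = r$polarity,
                        source_id = paste0("lib:", r$record_id),
                        formulas = if (!is.null(ff) && length(ff) == length(mz)) ff else NULL)
  ), class = "ms2_library_record")
}

#' Query library records by precursor m/z
#'
#' Returns every record whose stored precursor m/z is within `tol_ppm` of
#' `mz` (and matches `polarity` when given), ordered by record_id.
#'
#' @param library an `ms2_library` handle.
#' @param mz query precursor m/z (Th).
#' @param tol_ppm tolerance in ppm.
#' @param polarity optional `"positive"`/`"negative"` filter.
#' @param instrument_type,collision_energy optional exact-match filters.
#' @return list of `ms2_library_record`.
#' @export
query_by_precursor <- function(library, mz, tol_ppm, polarity = NULL,
                               instrument_type = NULL, collision_energy = NULL) {
  half <- mz * tol_ppm * 1e-6
  sql <- "SELECT * FROM spectra WHERE precursor_mz BETWEEN :lo AND :hi"
  params <- list(lo = mz - half, hi = mz + half)
  if (!is.null(polarity)) {
    sql <- paste(sql, "AND polarity = :pol"); params$pol <- polarity
  }
  if (!is.null(instrument_type)) {
    sql <- paste(sql, "AND instrument_type = :it"); params$it <- instrument_type
  }
  if (!is.null(collision_energy)) {
    sql <- paste(sql, "AND collision_energy = :ce"); params$ce <- collision_energy
  }
  sql <- paste(sql, "ORDER BY record_id")
  df <- DBI::dbGetQuery(library$con, sql, params = params)
  # re-check in ppm space (the Th window is symmetric around the query, the
  # ppm criterion is relative to the stored precursor; identical to within
  # rounding, asserted exactly here)
  keep <- abs(ppm_deviation(mz, df$precursor_mz)) <= tol_ppm |
    abs(ppm_deviation(df$precursor_mz, mz)) <= tol_ppm
  df <- df[keep, , drop = FALSE]
  lapply(seq_len(nrow(df)), function(i) row_to_record(df[i, , drop = FALSE]))
}

#' Query library records by exact neutral formula
#'
#' @param library an `ms2_library` handle.
#' @param formula formula string (compared after canonical reformatting).
#' @return list of `ms2_library_record`.
#' @export
query_by_formula <- function(library, formula) {
  canon <- format_formula(parse_formula(formula))
  df <- DBI::dbGetQuery(library$con,
                        "SELECT * FROM spectra WHERE formula = :f ORDER BY record_id",
                        params = list(f = canon))
  lapply(seq_len(nrow(df)), function(i) row_to_record(df[i, , drop = FALSE]))
}

#' All records of a library
#'
#' @param library an `ms2_library` handle.
#' @return list of `ms2_library_record`.
#' @export
library_records <- function(library) {
  df <- DBI::dbGetQuery(library$con, "SELECT * FROM spectra ORDER BY record_id")
  lapply(seq_len(nrow(df)), function(i) row_to_record(df[i, , drop = FALSE]))
}

#' Write records to a new SQLite library file
#'
#' @param records list of `ms2_library_record` (or lists with the same
#'   fields).
#' @param path output SQLite path (overwritten).
#' @return `path`, invisibly.
#' @export
write_library <- function(records, path) {
  if (file.exists(path)) unlink(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbExecute(con, paste(
    "CREATE TABLE spectra (record_id INTEGER PRIMARY KEY,",
    "compound_name TEXT, formula TEXT, inchikey TEXT, precursor_mz REAL,",
    "adduct TEXT, polarity TEXT, collision_energy TEXT,",
    "instrument_type TEXT, peaks_mz TEXT, peaks_intensity TEXT,",
    "fragment_formulas TEXT)"))
  DBI::dbExecute(con, "CREATE TABLE meta (key TEXT, value TEXT)")
  DBI::dbExecute(con, "INSERT INTO meta VALUES ('schema_version', :v)",
                 params = list(v = LIBRARY_SCHEMA_VERSION))
  DBI::dbExecute(con,
    "CREATE INDEX idx_spectra_precursor ON spectra (precursor_mz)")
  rows <- lapply(records, function(r) {
    s <- r$spectrum
    ff <- if (!is.null(s$formulas)) {
      paste(ifelse(is.na(s$formulas), "", s$formulas), collapse = ";")
    } else NA_character_
    data.frame(
      record_id = r$record_id, compound_name = r$compound_name,
      formula = r$formula, inchikey = r$inchikey,
      precursor_mz = r$precursor_mz, adduct = r$adduct,
      polarity = r$polarity, collision_energy = r$collision_energy,
      instrument_type = r$instrument_type,
      peaks_mz = paste(sprintf("%.6f", s$mz), collapse = ";"),
      peaks_intensity = paste(sprintf("%.6f", s$intensity), collapse = ";"),
      fragment_formulas = ff, stringsAsFactors = FALSE)
  })
  DBI::dbWriteTable(con, "spectra", do.call(rbind, rows), append = TRUE)
  invisible(path)
}

#' Derive the neutral-loss counterpart of a library
#'
#' Each record's spectrum is replaced by its neutral-loss mirror (precursor
#' minus fragment m/z, intensities unchanged); written as a new SQLite file
#' with the same schema.
#'
#' @param library an open `ms2_library`.
#' @param path output path for the neutral-loss library.
#' @return `path`, invisibly.
#' @export
derive_neutral_loss_library <- function(library, path) {
  recs <- library_records(library)
  nl <- lapply(recs, function(r) {
    r$spectrum <- neutral_loss_spectrum(r$spectrum)
    r
  })
  nl <- nl[vapply(nl, function(r) length(r$spectrum$mz) > 0, TRUE)]
  write_library(nl, path)
}
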