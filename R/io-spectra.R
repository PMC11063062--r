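# MGF and MSP peak-list readers/writers. Both dialects are line-oriented
# text; blocks are delimited by BEGIN IONS/END IONS (MGF) or started by
# "Name:" with a "Num Peaks:" count (MSP). RT units follow common tool
# conventions: RTINSECONDS (MGF) is seconds, RETENTIONTIME (MSP, MS-DIAL
# style) is minutes and converted to seconds on read.

#' Read spectra from an MGF or MSP file
#'
#' @param path file path.
#' @param dialect `"mgf"`, `"msp"`, or `"auto"` (by extension).
#' @param keep_empty keep blocks declaring zero peaks? Default drops them
#'   with a warning.
#' @return list of `ms2_spectrum`.
#' @export
read_spectra_file <- function(path, dialect = c("auto", "mgf", "msp"),
                              keep_empty = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext == "mgf") "mgf" else if (ext == "msp") "msp" else
      stop("cannot infer dialect from extension: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  if (dialect == "mgf") read_mgf_lines(lines, keep_empty)
  else read_msp_lines(lines, keep_empty)
}

read_mgf_lines <- function(lines, keep_empty) {
  starts <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(starts) != length(ends) ||
      (length(starts) && any(ends < starts))) {
    bad <- if (length(starts) > length(ends)) length(ends) + 1L else length(starts) + 1L
    stop("truncated MGF block at block index ", bad)
  }
  out <- list()
  for (b in seq_along(starts)) {
    body <- lines[(starts[b] + 1L):(ends[b] - 1L)]
    kv <- grepl("=", body, fixed = TRUE)
    meta <- body[kv]
    keys <- toupper(sub("=.*$", "", meta))
    vals <- sub("^[^=]*=", "", meta)
    get <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    pmz <- suppressWarnings(as.numeric(strsplit(get("PEPMASS"), "\\s+")[[1]][1]))
    rt <- suppressWarnings(as.numeric(get("RTINSECONDS")))  # already seconds
    charge <- get("CHARGE")
    pol <- if (!is.na(charge) && grepl("-", charge)) "negative" else "positive"
    pk_lines <- trimws(body[!kv])
    pk_lines <- pk_lines[nzchar(pk_lines)]
    pk <- do.call(rbind, lapply(pk_lines, function(l) {
      as.numeric(strsplit(l, "[\\s\t]+", perl = TRUE)[[1]][1:2])
    }))
    if (is.null(pk) || !nrow(pk)) {
      if (keep_empty) {
        out[[length(out) + 1L]] <- spectrum(numeric(0), numeric(0),
                                            precursor_mz = pmz, precursor_rt = rt,
                                            polarity = pol,
                                            source_id = get("TITLE"))
      } else warning("empty MGF block ", b, " excluded", call. = FALSE)
      next
    }
    if (any(is.na(pk))) stop("unparseable peak line in MGF block ", b)
    out[[length(out) + 1L]] <- spectrum(pk[, 1], pk[, 2], precursor_mz = pmz,
                                        precursor_rt = rt, polarity = pol,
                                        source_id = get("TITLE"))
  }
  out
}

read_msp_lines <- function(lines, keep_empty) {
  starts <- grep("^Name:", lines, ignore.case = TRUE)
  out <- list()
  bounds <- c(starts, length(lines) + 1L)
  for (b in seq_along(starts)) {
    body <- lines[starts[b]:(bounds[b + 1L] - 1L)]
    kv_idx <- grep("^[A-Za-z][A-Za-z0-9_ ]*:", body)
    keys <- toupper(trimws(sub(":.*$", "", body[kv_idx])))
    vals <- trimws(sub("^[^:]*:", "", body[kv_idx]))
    get <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    np <- suppressWarnings(as.integer(get("NUM PEAKS")))
    if (is.na(np)) stop("MSP block ", b, " lacks a Num Peaks field")
    pk_start <- kv_idx[match("NUM PEAKS", keys)] + 1L
    pk_lines <- trimws(body[seq_len(length(body)) >= pk_start])
    pk_lines <- pk_lines[nzchar(pk_lines)]
    if (length(pk_lines) < np) stop("truncated MSP block at block index ", b)
    pmz <- suppressWarnings(as.numeric(get("PRECURSORMZ")))
    rt_min <- suppressWarnings(as.numeric(get("RETENTIONTIME")))
    rt <- if (!is.na(rt_min)) rt_min * 60 else NA_real_  # minutes -> seconds
    pol_raw <- get("IONMODE")
    pol <- if (!is.na(pol_raw) && grepl("^n", tolower(pol_raw))) "negative" else "positive"
    if (np == 0L) {
      if (keep_empty) {
        out[[length(out) + 1L]] <- spectrum(numeric(0), numeric(0),
                                            precursor_mz = pmz, precursor_rt = rt,
                                            polarity = pol, source_id = get("NAME"))
      } else warning("MSP block ", b, " has zero peaks; excluded", call. = FALSE)
      next
    }
    pk <- do.call(rbind, lapply(pk_lines[seq_len(np)], function(l) {
      as.numeric(strsplit(l, "[\\s\t;]+", perl = TRUE)[[1]][1:2])
    }))
    if (any(is.na(pk))) stop("unparseable peak line in MSP block ", b)
    out[[length(out) + 1L]] <- spectrum(pk[, 1], pk[, 2], precursor_mz = pmz,
                                        precursor_rt = rt, polarity = pol,
                                        source_id = get("NAME"))
  }
  out
}

#' Write spectra to an MGF or MSP file
#'
#' m/z values are written with six decimal places so that a read/write cycle
#' preserves them to 1e-6 Th.
#'
#' @param spectra list of `ms2_spectrum`.
#' @param path output path.
#' @param dialect `"mgf"` or `"msp"` (default by extension).
#' @return `path`, invisibly.
#' @export
write_spectra_file <- function(spectra, path, dialect = c("auto", "mgf", "msp")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext == "msp") "msp" else "mgf"
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    id <- if (is.na(s$source_id)) paste0("spectrum_", i) else s$source_id
    if (dialect == "mgf") {
      writeLines("BEGIN IONS", con)
      writeLines(paste0("TITLE=", id), con)
      if (is.finite(s$precursor_mz))
        writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
      if (is.finite(s$precursor_rt))
        writeLines(sprintf("RTINSECONDS=%.3f", s$precursor_rt), con)
      writeLines(paste0("CHARGE=1", if (identical(s$polarity, "negative")) "-" else "+"), con)
      writeLines(sprintf("%.6f %.6f", s$mz, s$intensity), con)
      writeLines(c("END IONS", ""), con)
    } else {
      writeLines(paste0("Name: ", id), con)
      if (is.finite(s$precursor_mz))
        writeLines(sprintf("PRECURSORMZ: %.6f", s$precursor_mz), con)
      if (is.finite(s$precursor_rt))
        writeLines(sprintf("RETENTIONTIME: %.5f", s$precursor_rt / 60), con)
      writeLines(paste0("Ionmode: ", s$polarity), con)
      writeLines(paste0("Num Peaks: ", length(s$mz)), con)
      if (length(s$mz)) writeLines(sprintf("%.6f\t%.6f", s$mz, s$intensity), con)
      writeLines("", con)
    }
  }
  invisible(path)
}
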