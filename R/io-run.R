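# mzML/mzXML reading and writing through the mzR backend. A run is held in
# memory as time-ordered lists of MS1 and MS2 spectra; for scan spectra the
# `precursor_rt` slot carries the scan retention time.

DEFAULT_ISOLATION_HALFWIDTH <- 0.75  # Th; typical DDA quadrupole default

#' Construct an in-memory LC-MS run
#'
#' @param ms1 list of MS1 `ms2_spectrum` scans (centroids; `precursor_rt` =
#'   scan RT).
#' @param ms2 list of MS2 `ms2_spectrum` scans with precursor and isolation
#'   metadata.
#' @return an object of class `ms2_run`, scans sorted by RT.
#' @export
ms_run <- function(ms1 = list(), ms2 = list()) {
  rt1 <- vapply(ms1, `[[`, 1.0, "precursor_rt")
  rt2 <- vapply(ms2, `[[`, 1.0, "precursor_rt")
  structure(list(ms1 = ms1[order(rt1)], ms2 = ms2[order(rt2)]),
            class = "ms2_run")
}

#' @export
print.ms2_run <- function(x, ...) {
  cat(sprintf("<ms2_run> %d MS1 scans, %d MS2 scans\n",
              length(x$ms1), length(x$ms2)))
  invisible(x)
}

#' Read a centroided mzML/mzXML run
#'
#' MS2 scans carry precursor m/z, the scan RT, isolation-window bounds (from
#' file metadata when present, else a fallback of precursor +/- 0.75 Th with
#' a warning) and, for DIA data, a SWATH window index derived by grouping
#' identical isolation windows in ascending lower-bound order. Profile-mode
#' scans are rejected.
#'
#' @param path mzML or mzXML file.
#' @param level_filter optional integer vector of MS levels to keep.
#' @param fallback_halfwidth isolation half-width (Th) used when the file
#'   lacks isolation metadata.
#' @return an `ms2_run`.
#' @export
read_ms_run <- function(path, level_filter = NULL,
                        fallback_halfwidth = DEFAULT_ISOLATION_HALFWIDTH) {
  if (!file.exists(path)) stop("file not found: ", path)
  fh <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop("unreadable MS file: ", path,
                                          " (", conditionMessage(e), ")"))
  on.exit(mzR::close(fh))
  hdr <- mzR::header(fh)
  if (any(!is.na(hdr$centroided) & !hdr$centroided)) {
    stop("profile-mode scans present; centroid the data first")
  }
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  ms1 <- list(); ms2 <- list()
  warned_fallback <- FALSE
  pol_of <- function(p) if (!is.na(p) && p < 0) "negative" else "positive"
  for (i in seq_len(nrow(hdr))) {
    lv <- hdr$msLevel[i]
    if (!is.null(level_filter) && !(lv %in% level_filter)) next
    m <- pk[[i]]
    s_mz <- if (nrow(m)) m[, 1] else numeric(0)
    s_int <- if (nrow(m)) m[, 2] else numeric(0)
    if (lv == 1L) {
      ms1[[length(ms1) + 1L]] <- spectrum(
        s_mz, s_int, precursor_rt = hdr$retentionTime[i], ms_level = 1L,
        polarity = pol_of(hdr$polarity[i]),
        source_id = as.character(hdr$acquisitionNum[i]))
    } else {
      pmz <- hdr$precursorMZ[i]
      tgt <- hdr$isolationWindowTargetMZ[i]
      lo_off <- hdr$isolationWindowLowerOffset[i]
      hi_off <- hdr$isolationWindowUpperOffset[i]
      if (is.na(tgt) || is.na(lo_off) || is.na(hi_off)) {
        if (!warned_fallback) {
          warning("missing isolation-window metadata; using precursor +/- ",
                  fallback_halfwidth, " Th", call. = FALSE)
          warned_fallback <- TRUE
        }
        lo <- pmz - fallback_halfwidth
        hi <- pmz + fallback_halfwidth
      } else {
        lo <- tgt - lo_off
        hi <- tgt + hi_off
      }
      ms2[[length(ms2) + 1L]] <- spectrum(
        s_mz, s_int, precursor_mz = pmz, precursor_rt = hdr$retentionTime[i],
        ms_level = 2L, polarity = pol_of(hdr$polarity[i]),
        source_id = as.character(hdr$acquisitionNum[i]),
        isolation_lower = lo, isolation_upper = hi)
    }
  }
  # SWATH window index: group identical isolation windows, order by lower bound
  if (length(ms2)) {
    lows <- vapply(ms2, `[[`, 1.0, "isolation_lower")
    highs <- vapply(ms2, `[[`, 1.0, "isolation_upper")
    key <- paste(round(lows, 4), round(highs, 4))
    uniq <- unique(data.frame(key = key, low = lows, stringsAsFactors = FALSE))
    uniq <- uniq[order(uniq$low), , drop = FALSE]
    idx <- match(key, uniq$key)
    for (j in seq_along(ms2)) ms2[[j]]$window_index <- idx[j]
  }
  ms_run(ms1, ms2)
}

#' Write an in-memory run to mzML
#'
#' Inverse of [read_ms_run()]: scans are interleaved in RT order and written
#' with precursor and isolation-window metadata via mzR.
#'
#' @param run an `ms2_run`.
#' @param path output mzML path.
#' @return `path`, invisibly.
#' @export
write_ms_run <- function(run, path) {
  scans <- c(run$ms1, run$ms2)
  rts <- vapply(scans, `[[`, 1.0, "precursor_rt")
  scans <- scans[order(rts, vapply(scans, `[[`, 1L, "ms_level"))]
  n <- length(scans)
  if (!n) stop("empty run")
  pol_num <- function(p) if (identical(p, "negative")) -1L else 1L
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = vapply(scans, `[[`, 1L, "ms_level"),
    polarity = vapply(scans, function(s) pol_num(s$polarity), 1L),
    peaksCount = vapply(scans, function(s) length(s$mz), 1L),
    totIonCurrent = vapply(scans, function(s) sum(s$intensity), 1.0),
    retentionTime = vapply(scans, `[[`, 1.0, "precursor_rt"),
    basePeakMZ = vapply(scans, function(s)
      if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, 1.0),
    basePeakIntensity = vapply(scans, function(s)
      if (length(s$mz)) max(s$intensity) else 0, 1.0),
    collisionEnergy = vapply(scans, function(s)
      if (s$ms_level == 2L) 30.0 else NA_real_, 1.0),
    ionisationEnergy = 0,
    lowMZ = vapply(scans, function(s) if (length(s$mz)) min(s$mz) else 0, 1.0),
    highMZ = vapply(scans, function(s) if (length(s$mz)) max(s$mz) else 0, 1.0),
    precursorScanNum = 0L,
    precursorMZ = vapply(scans, function(s)
      if (s$ms_level == 2L) s$precursor_mz else 0, 1.0),
    precursorCharge = vapply(scans, function(s)
      if (s$ms_level == 2L) 1L else 0L, 1L),
    precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = vapply(scans, function(s)
      if (s$ms_level == 2L) s$precursor_mz else NA_real_, 1.0),
    isolationWindowLowerOffset = vapply(scans, function(s)
      if (s$ms_level == 2L && is.finite(s$isolation_lower))
        s$precursor_mz - s$isolation_lower else NA_real_, 1.0),
    isolationWindowUpperOffset = vapply(scans, function(s)
      if (s$ms_level == 2L && is.finite(s$isolation_upper))
        s$isolation_upper - s$precursor_mz else NA_real_, 1.0),
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  pks <- lapply(scans, function(s) cbind(mz = s$mz, intensity = s$intensity))
  mzR::writeMSData(object = pks, file = path, header = hdr)
  invisible(path)
}
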