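#' Construct a centroided fragment spectrum
#'
#' A spectrum is the universal currency of the pipeline: a peak list of
#' fragment m/z and intensity values plus precursor metadata. Fragments are
#' stored sorted ascending by m/z; centroids closer than `merge_tol` Thomson
#' are merged by intensity sum (intensity-weighted mean m/z), which absorbs
#' duplicate centroids produced by instrument export.
#'
#' @param mz numeric vector of fragment m/z values (Th), all > 0.
#' @param intensity numeric vector of non-negative abundances.
#' @param precursor_mz precursor m/z (Th) or `NA`.
#' @param precursor_rt precursor retention time in seconds or `NA`.
#' @param ms_level 1 or 2.
#' @param polarity `"positive"` or `"negative"`.
#' @param source_id opaque scan/record identifier.
#' @param formulas optional character vector of per-fragment elemental
#'   formulas (recycled to length after merging only when lengths match).
#' @param isolation_lower,isolation_upper isolation window bounds (Th) for
#'   MS2 scans, or `NA`.
#' @param window_index SWATH window index for DIA scans, or `NA`.
#' @param merge_tol m/z tolerance (Th) below which centroids are merged.
#' @return an object of class `ms2_spectrum`.
#' @export
spectrum <- function(mz, intensity, precursor_mz = NA_real_,
                     precursor_rt = NA_real_, ms_level = 2L,
                     polarity = "positive", source_id = NA_character_,
                     formulas = NULL,
                     isolation_lower = NA_real_, isolation_upper = NA_real_,
                     window_index = NA_integer_, merge_tol = 1e-4) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz)) {
    if (any(!is.finite(mz)) || any(mz <= 0)) stop("fragment m/z must be finite and > 0")
    if (any(!is.finite(intensity)) || any(intensity < 0)) stop("intensities must be finite and >= 0")
  }
  if (!is.null(formulas) && length(formulas) != length(mz)) {
    stop("formulas must match fragment count")
  }
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (!is.null(formulas)) formulas <- formulas[o]
  if (length(mz) > 1L) {
    grp <- cumsum(c(TRUE, diff(mz) > merge_tol))
    if (max(grp) < length(mz)) {
      w <- intensity
      # zero-intensity duplicates: plain mean to avoid 0/0
      msum <- tapply(w, grp, sum)
      mz_new <- as.numeric(tapply(seq_along(mz), grp, function(i) {
        if (sum(w[i]) > 0) sum(mz[i] * w[i]) / sum(w[i]) else mean(mz[i])
      }))
      int_new <- as.numeric(msum)
      if (!is.null(formulas)) {
        formulas <- as.character(tapply(seq_along(mz), grp, function(i) {
          formulas[i][which.max(w[i])]
        }))
      }
      mz <- mz_new; intensity <- int_new
    }
  }
  structure(list(
    mz = as.numeric(mz), intensity = as.numeric(intensity),
    precursor_mz = as.numeric(precursor_mz),
    precursor_rt = as.numeric(precursor_rt),
    ms_level = as.integer(ms_level), polarity = polarity,
    source_id = source_id, formulas = formulas,
    isolation_lower = as.numeric(isolation_lower),
    isolation_upper = as.numeric(isolation_upper),
    window_index = as.integer(window_index)
  ), class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum> MS%d, %d fragments", x$ms_level, length(x$mz)))
  if (is.finite(x$precursor_mz)) cat(sprintf(", precursor %.4f Th", x$precursor_mz))
  if (is.finite(x$precursor_rt)) cat(sprintf(" @ %.1f s", x$precursor_rt))
  cat("\n")
  if (length(x$mz)) {
    n <- min(length(x$mz), 8L)
    for (i in seq_len(n)) cat(sprintf("  %10.4f  %12.2f\n", x$mz[i], x$intensity[i]))
    if (length(x$mz) > n) cat(sprintf("  ... %d more\n", length(x$mz) - n))
  }
  invisible(x)
}

#' @export
length.ms2_spectrum <- function(x) length(x$mz)

is_spectrum <- function(x) inherits(x, "ms2_spectrum")

#' Normalize a spectrum to base peak 100
#'
#' Rescales intensities so the most intense fragment equals 100; relative
#' intensities and fragment order are preserved. Idempotent and
#' scale-invariant.
#'
#' @param s an `ms2_spectrum`.
#' @return the normalized spectrum.
#' @export
normalize_spectrum <- function(s) {
  stopifnot(is_spectrum(s))
  if (!length(s$mz)) stop("cannot normalize an empty spectrum")
  m <- max(s$intensity)
  if (m <= 0) stop("cannot normalize a spectrum with all-zero intensities")
  s$intensity <- s$intensity / m * 100
  s
}

#' Parts-per-million deviation between two m/z values
#'
#' @param mz observed m/z.
#' @param ref reference m/z.
#' @return signed deviation in ppm, `1e6 * (mz - ref) / ref`.
#' @export
ppm_deviation <- function(mz, ref) 1e6 * (mz - ref) / ref

#' Match fragments of two spectra at an m/z tolerance
#'
#' Greedy nearest-m/z pairing used by the similarity metrics and design-matrix
#' alignment. Returns an aligned m/z axis (union of peaks merged at `mz_tol`)
#' and the intensity of each spectrum on that axis (0 where absent).
#'
#' @param spectra list of `ms2_spectrum`.
#' @param mz_tol alignment tolerance in Th.
#' @return list with `axis` (numeric m/z bins) and `intensity` (matrix, one
#'   column per input spectrum).
#' @export
align_spectra <- function(spectra, mz_tol = 0.01) {
  stopifnot(length(spectra) >= 1L)
  all_mz <- unlist(lapply(spectra, `[[`, "mz"))
  all_int <- unlist(lapply(spectra, `[[`, "intensity"))
  src <- rep(seq_along(spectra), vapply(spectra, function(s) length(s$mz), 1L))
  if (!length(all_mz)) {
    return(list(axis = numeric(0),
                intensity = matrix(0, 0, length(spectra))))
  }
  o <- order(all_mz)
  all_mz <- all_mz[o]; all_int <- all_int[o]; src <- src[o]
  grp <- cumsum(c(TRUE, diff(all_mz) > mz_tol))
  ngrp <- max(grp)
  axis <- as.numeric(tapply(seq_along(all_mz), grp, function(i) {
    if (sum(all_int[i]) > 0) sum(all_mz[i] * all_int[i]) / sum(all_int[i]) else mean(all_mz[i])
  }))
  M <- matrix(0, ngrp, length(spectra))
  for (k in seq_along(all_mz)) {
    M[grp[k], src[k]] <- M[grp[k], src[k]] + all_int[k]
  }
  list(axis = axis, intensity = M)
}

#' Construct an MS1 feature table
#'
#' @param mz_med,rt_med median m/z (Th) and retention time (s).
#' @param mz_min,mz_max,rt_min,rt_max optional ranges; when `NA` they can be
#'   derived downstream from ppm / RT tolerances.
#' @param intensity feature abundance.
#' @param feature_id optional identifiers (default `F1`, `F2`, ...).
#' @return a `data.frame` with class `ms1_features`.
#' @export
ms1_features <- function(mz_med, rt_med, mz_min = NA_real_, mz_max = NA_real_,
                         rt_min = NA_real_, rt_max = NA_real_,
                         intensity = NA_real_, feature_id = NULL) {
  n <- length(mz_med)
  if (is.null(feature_id)) feature_id <- paste0("F", seq_len(n))
  df <- data.frame(feature_id = as.character(feature_id),
                   mz_med = mz_med, rt_med = rt_med,
                   mz_min = rep_len(mz_min, n), mz_max = rep_len(mz_max, n),
                   rt_min = rep_len(rt_min, n), rt_max = rep_len(rt_max, n),
                   intensity = rep_len(intensity, n),
                   stringsAsFactors = FALSE)
  ok <- with(df, (is.na(mz_min) | mz_min <= mz_med) & (is.na(mz_max) | mz_med <= mz_max) &
               (is.na(rt_min) | rt_min <= rt_med) & (is.na(rt_max) | rt_med <= rt_max))
  if (!all(ok)) stop("feature ranges must bracket the medians")
  class(df) <- c("ms1_features", "data.frame")
  df
}

#' Read or write a delimited MS1 feature table
#'
#' Comma- or tab-separated text with columns `mz_med, rt_med, mz_min, mz_max,
#' rt_min, rt_max, intensity` (missing range columns allowed).
#'
#' @param path file path.
#' @return for `read_feature_table`, an `ms1_features` data frame.
#' @export
read_feature_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("mz_med", "rt_med")
  if (!all(need %in% names(df))) stop("feature table needs mz_med and rt_med columns")
  for (col in c("mz_min", "mz_max", "rt_min", "rt_max", "intensity")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  ms1_features(df$mz_med, df$rt_med, df$mz_min, df$mz_max, df$rt_min,
               df$rt_max, df$intensity,
               feature_id = if ("feature_id" %in% names(df)) df$feature_id else NULL)
}

#' @rdname read_feature_table
#' @param features an `ms1_features` table.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}
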