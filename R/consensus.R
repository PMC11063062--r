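# Replicate consensus: collapse the deconvolved spectra of one feature
# across replicates into a single spectrum using fragment frequency, with an
# optional database-assisted rescue for low-frequency fragments that match a
# reference spectrum of the same precursor.

#' Consensus spectrum across replicates
#'
#' With a single input spectrum the step is skipped and the spectrum
#' returned normalized. Otherwise fragments are grouped across replicates at
#' `mz_tol`; a group is kept when its frequency `count / n_replicates` is at
#' least `freq_threshold`, or - when `db_assist` is on - when its m/z
#' matches any fragment of the reference list L (all library spectra at the
#' precursor) at `mz_tol` and it was seen in at least two replicates. Kept
#' groups are merged (intensity-weighted mean m/z, mean of per-replicate
#' normalized intensities) and the result normalized.
#'
#' @param spectra non-empty list of `ms2_spectrum` replicates of one
#'   feature.
#' @param mz_tol fragment grouping tolerance (Th).
#' @param freq_threshold fraction in `[0, 1]` (e.g. 0.5).
#' @param db_assist enable database-assisted rescue.
#' @param library an open `ms2_library` (required when `db_assist`).
#' @param precursor_mz precursor m/z used to extract L (defaults to the
#'   first spectrum's precursor).
#' @param ppm_tol precursor tolerance (ppm) for extracting L.
#' @return the consensus `ms2_spectrum`.
#' @export
consensus_spectrum <- function(spectra, mz_tol = 0.01, freq_threshold = 0.5,
                               db_assist = FALSE, library = NULL,
                               precursor_mz = NULL, ppm_tol = 10) {
  if (!length(spectra)) stop("no spectra for consensus")
  if (length(spectra) == 1L) return(normalize_spectrum(spectra[[1]]))
  if (db_assist && is.null(library)) stop("db_assist requires a library")
  n_rep <- length(spectra)
  spectra <- lapply(spectra, normalize_spectrum)
  al <- align_spectra(spectra, mz_tol)
  counts <- rowSums(al$intensity > 0)
  keep <- counts / n_rep >= freq_threshold
  if (db_assist) {
    pmz <- if (!is.null(precursor_mz)) precursor_mz else spectra[[1]]$precursor_mz
    if (!is.finite(pmz)) stop("db_assist needs a precursor m/z")
    L <- query_by_precursor(library, pmz, ppm_tol)
    lib_mz <- sort(unlist(lapply(L, function(r) r$spectrum$mz)))
    if (length(lib_mz)) {
      in_lib <- vapply(al$axis, function(m) any(abs(lib_mz - m) <= mz_tol), TRUE)
      keep <- keep | (in_lib & counts >= 2)
    }
  }
  if (!any(keep)) stop("consensus removed every fragment")
  mean_int <- rowSums(al$intensity[keep, , drop = FALSE]) / n_rep
  s1 <- spectra[[1]]
  out <- spectrum(al$axis[keep], mean_int, precursor_mz = s1$precursor_mz,
                  precursor_rt = s1$precursor_rt, polarity = s1$polarity,
                  source_id = s1$source_id)
  normalize_spectrum(out)
}
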