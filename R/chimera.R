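# Chimera assessment for DDA runs: assign MS2 scans to MS1 features, merge
# co-assigned scans, and classify each feature's spectrum as clean or
# chimeric from the centroids of the nearest MS1 scan.

# a contaminant centroid closer than this to the main ion is the same
# centroid reported twice (instrument merge artifact)
MAIN_ION_MERGE_TOL <- 1e-3

#' Assign MS2 scans to MS1 features
#'
#' A scan is assigned to a feature when its precursor m/z falls inside the
#' feature's m/z range and its RT inside the feature's RT range. Features
#' lacking explicit ranges get `mz_med * (1 -/+ ppm_tol*1e-6)` and
#' `rt_med -/+ rt_tol`. One scan may be assigned to several features.
#'
#' @param run an `ms2_run` with DDA MS2 scans.
#' @param features an `ms1_features` table.
#' @param ppm_tol m/z tolerance (ppm) for features without ranges.
#' @param rt_tol RT tolerance (s) for features without ranges.
#' @return named list (by `feature_id`) of lists of `ms2_spectrum`;
#'   unassigned-scan count is attached as attribute `n_unassigned`.
#' @export
assign_ms2_to_features <- function(run, features, ppm_tol = 10, rt_tol = 15) {
  stopifnot(nrow(features) >= 1)
  f <- as.data.frame(features)
  f$mz_min <- ifelse(is.na(f$mz_min), f$mz_med * (1 - ppm_tol * 1e-6), f$mz_min)
  f$mz_max <- ifelse(is.na(f$mz_max), f$mz_med * (1 + ppm_tol * 1e-6), f$mz_max)
  f$rt_min <- ifelse(is.na(f$rt_min), f$rt_med - rt_tol, f$rt_min)
  f$rt_max <- ifelse(is.na(f$rt_max), f$rt_med + rt_tol, f$rt_max)
  out <- stats::setNames(vector("list", nrow(f)), f$feature_id)
  assigned <- logical(length(run$ms2))
  for (i in seq_len(nrow(f))) {
    hits <- list()
    for (k in seq_along(run$ms2)) {
      s <- run$ms2[[k]]
      if (s$precursor_mz >= f$mz_min[i] && s$precursor_mz <= f$mz_max[i] &&
          s$precursor_rt >= f$rt_min[i] && s$precursor_rt <= f$rt_max[i]) {
        hits[[length(hits) + 1L]] <- s
        assigned[k] <- TRUE
      }
    }
    out[[i]] <- hits
  }
  attr(out, "n_unassigned") <- sum(!assigned)
  out
}

#' Merge co-assigned MS2 scans into one spectrum
#'
#' Fragments are grouped across scans at `mz_tol`; each group's m/z is the
#' intensity-weighted mean and its intensity the sum (MZmine-style weighted
#' merge). The result is normalized to base peak 100.
#'
#' @param spectra non-empty list of `ms2_spectrum` for one feature.
#' @param mz_tol grouping tolerance (Th).
#' @return a single merged, normalized `ms2_spectrum`.
#' @export
merge_coassigned_spectra <- function(spectra, mz_tol = 0.01) {
  if (!length(spectra)) stop("no spectra to merge")
  al <- align_spectra(spectra, mz_tol)
  tot <- rowSums(al$intensity)
  s1 <- spectra[[1L]]
  merged <- spectrum(al$axis, tot, precursor_mz = s1$precursor_mz,
                     precursor_rt = stats::median(vapply(spectra, `[[`, 1.0,
                                                         "precursor_rt")),
                     polarity = s1$polarity, source_id = s1$source_id,
                     isolation_lower = s1$isolation_lower,
                     isolation_upper = s1$isolation_upper)
  normalize_spectrum(merged)
}

#' Classify a feature's MS2 spectrum as clean or chimeric
#'
#' Uses the MS1 scan nearest in RT to the MS2 scan (ties break to the
#' earlier scan). The in-window centroid closest in m/z to the feature's
#' `mz_med` is the main ion; any other in-window centroid above
#' `intensity_threshold` is a contamination ion, and their presence makes
#' the spectrum chimeric.
#'
#' @param feature one row of an `ms1_features` table.
#' @param spectrum0 the feature's (merged) MS2 spectrum.
#' @param run the `ms2_run` providing MS1 scans.
#' @param intensity_threshold absolute acquisition intensity threshold;
#'   contaminants at or below it are ignored.
#' @param window_override optional `c(lower, upper)` isolation bounds taking
#'   priority over scan metadata.
#' @param relative_threshold when `TRUE`, `intensity_threshold` is a
#'   fraction of the main-ion intensity instead of an absolute abundance.
#' @return an object of class `chimera_assessment` with fields `feature`,
#'   `spectrum0`, `main_ion`, `contamination_ions`, `is_chimeric`,
#'   `isolation_low`, `isolation_high`, `nearest_ms1_rt`, `no_ms1_centroid`.
#' @export
assess_chimeric <- function(feature, spectrum0, run, intensity_threshold = 1e4,
                            window_override = NULL, relative_threshold = FALSE) {
  if (!length(run$ms1)) stop("run has no MS1 scans")
  if (!is.null(window_override)) {
    lo <- window_override[1]; hi <- window_override[2]
  } else if (is.finite(spectrum0$isolation_lower) &&
             is.finite(spectrum0$isolation_upper)) {
    lo <- spectrum0$isolation_lower; hi <- spectrum0$isolation_upper
  } else {
    lo <- feature$mz_med - DEFAULT_ISOLATION_HALFWIDTH
    hi <- feature$mz_med + DEFAULT_ISOLATION_HALFWIDTH
  }
  rts <- vapply(run$ms1, `[[`, 1.0, "precursor_rt")
  target_rt <- if (is.finite(spectrum0$precursor_rt)) spectrum0$precursor_rt else feature$rt_med
  # which.min returns the first index on ties = the earlier scan
  nearest <- run$ms1[[which.min(abs(rts - target_rt))]]
  in_win <- which(nearest$mz >= lo & nearest$mz <= hi)
  no_centroid <- FALSE
  if (!length(in_win)) {
    warning("no MS1 centroid inside the isolation window; using feature values",
            call. = FALSE)
    no_centroid <- TRUE
    main <- c(mz = feature$mz_med, intensity = feature$intensity)
    contam <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("mz", "intensity")))
  } else {
    main_idx <- in_win[which.min(abs(nearest$mz[in_win] - feature$mz_med))]
    main <- c(mz = nearest$mz[main_idx], intensity = nearest$intensity[main_idx])
    others <- setdiff(in_win, main_idx)
    others <- others[abs(nearest$mz[others] - main[["mz"]]) > MAIN_ION_MERGE_TOL]
    thr <- if (relative_threshold) intensity_threshold * main[["intensity"]] else intensity_threshold
    others <- others[nearest$intensity[others] > thr]
    contam <- cbind(mz = nearest$mz[others], intensity = nearest$intensity[others])
  }
  structure(list(
    feature = feature, spectrum0 = spectrum0, main_ion = main,
    contamination_ions = contam, is_chimeric = nrow(contam) > 0,
    isolation_low = lo, isolation_high = hi,
    nearest_ms1_rt = nearest$precursor_rt, nearest_ms1 = nearest,
    no_ms1_centroid = no_centroid
  ), class = "chimera_assessment")
}

#' @export
print.chimera_assessment <- function(x, ...) {
  cat(sprintf("<chimera_assessment> feature %s: %s\n",
              x$feature$feature_id,
              if (x$is_chimeric) sprintf("chimeric (%d contaminant%s)",
                                         nrow(x$contamination_ions),
                                         if (nrow(x$contamination_ions) > 1) "s" else "")
              else "clean"))
  cat(sprintf("  main ion %.4f Th (intensity %.3g), window [%.3f, %.3f]\n",
              x$main_ion[["mz"]], x$main_ion[["intensity"]],
              x$isolation_low, x$isolation_high))
  invisible(x)
}
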