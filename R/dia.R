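# SWATH-DIA pseudo-MS2 reconstruction: extract fragment EICs from the
# feature's SWATH window, detect chromatographic peaks, cluster them by apex
# RT and peak-shape correlation, pick a model peak per cluster, decompose
# every EIC as a non-negative combination of the model-peak traces, and
# export the cluster co-eluting with the MS1 feature as a pseudo-MS2
# spectrum.

#' Resolve the SWATH window containing a precursor
#'
#' Overlapping windows are resolved to the one whose center is nearest the
#' precursor, so a precursor is never assigned to two windows.
#'
#' @param run an `ms2_run` with DIA scans.
#' @param precursor_mz precursor m/z (Th).
#' @return the window index.
#' @export
swath_window_of <- function(run, precursor_mz) {
  if (!length(run$ms2)) stop("run has no MS2 scans")
  lows <- vapply(run$ms2, `[[`, 1.0, "isolation_lower")
  highs <- vapply(run$ms2, `[[`, 1.0, "isolation_upper")
  idx <- vapply(run$ms2, `[[`, 1L, "window_index")
  win <- unique(data.frame(idx = idx, low = lows, high = highs))
  hit <- win[win$low <= precursor_mz & precursor_mz <= win$high, , drop = FALSE]
  if (!nrow(hit)) {
    stop(sprintf("precursor %.4f outside all SWATH windows [%s]", precursor_mz,
                 paste(sprintf("%.1f-%.1f", win$low, win$high), collapse = ", ")))
  }
  centers <- (hit$low + hit$high) / 2
  hit$idx[which.min(abs(centers - precursor_mz))]
}

#' Extract fragment EICs for a feature from its SWATH window
#'
#' Fragment m/z values across the window's scans are binned at `mz_tol`;
#' each bin yields one extracted ion chromatogram over the feature's RT
#' range padded by `rt_pad` seconds on both sides.
#'
#' @param run an `ms2_run` with DIA scans.
#' @param feature one row of an `ms1_features` table.
#' @param mz_tol fragment binning tolerance (Th).
#' @param rt_pad padding (s) around the feature RT range (about one peak
#'   width).
#' @return list of EICs, each `list(fragment_mz, rt, intensity,
#'   window_index)`.
#' @export
extract_ms2_eics <- function(run, feature, mz_tol = 0.01, rt_pad = 15) {
  wi <- swath_window_of(run, feature$mz_med)
  scans <- run$ms2[vapply(run$ms2, `[[`, 1L, "window_index") == wi]
  rts <- vapply(scans, `[[`, 1.0, "precursor_rt")
  rt_lo <- (if (is.na(feature$rt_min)) feature$rt_med else feature$rt_min) - rt_pad
  rt_hi <- (if (is.na(feature$rt_max)) feature$rt_med else feature$rt_max) + rt_pad
  sel <- rts >= rt_lo & rts <= rt_hi
  scans <- scans[sel]; rts <- rts[sel]
  if (!length(scans)) return(list())
  o <- order(rts)
  scans <- scans[o]; rts <- rts[o]
  all_mz <- sort(unique(unlist(lapply(scans, `[[`, "mz"))))
  if (!length(all_mz)) return(list())
  grp <- cumsum(c(TRUE, diff(all_mz) > mz_tol))
  centers <- as.numeric(tapply(all_mz, grp, mean))
  eics <- lapply(seq_along(centers), function(g) {
    trace <- vapply(scans, function(s) {
      hit <- abs(s$mz - centers[g]) <= mz_tol
      if (any(hit)) sum(s$intensity[hit]) else 0
    }, 1.0)
    list(fragment_mz = centers[g], rt = rts, intensity = trace,
         window_index = wi)
  })
  eics
}

# chromatographic peak detection on one EIC: Savitzky-Golay smoothing, local
# maxima, prominence >= 3x the MAD of the trace (noise proxy)
detect_eic_peak <- function(eic, sg_width = 5) {
  y <- eic$intensity
  n <- length(y)
  if (n < 3 || max(y) <= 0) return(NULL)
  ys <- if (n >= sg_width) {
    as.numeric(signal::sgolayfilt(y, p = 2, n = sg_width))
  } else y
  ys <- pmax(ys, 0)
  noise <- stats::mad(y[y < stats::quantile(y, 0.5) + 1e-12], constant = 1.4826)
  if (!is.finite(noise)) noise <- 0
  apex <- which.max(ys)
  prominence <- max(ys) - min(ys)
  if (prominence <= 1e-6 * max(ys)) return(NULL)  # flat trace: no peak
  if (noise > 0 && prominence < 3 * noise) return(NULL)
  half <- max(ys) / 2
  lo <- apex; while (lo > 1 && ys[lo - 1] > half) lo <- lo - 1
  hi <- apex; while (hi < n && ys[hi + 1] > half) hi <- hi + 1
  list(apex_rt = eic$rt[apex], apex_intensity = y[apex],
       bounds = c(eic$rt[lo], eic$rt[hi]), smoothed = ys)
}

#' Detect and cluster chromatographic peaks across fragment EICs
#'
#' Each EIC's peak is detected by Savitzky-Golay-smoothed local-maximum
#' search with a prominence rule; EICs without a detectable peak are
#' discarded. Peaks are grouped when their apexes are within `rt_tol` and
#' their traces correlate (Pearson) at or above `shape_corr_min` with the
#' group's founding member. The model peak of a cluster is its most intense
#' member.
#'
#' @param eics list of EICs from [extract_ms2_eics()].
#' @param shape_corr_min minimum Pearson shape correlation in `[0, 1]`.
#' @param rt_tol apex RT tolerance (s).
#' @return list of clusters, each `list(members, eic_index, apex_rt,
#'   model_peak)` where `model_peak` indexes into `members`.
#' @export
detect_and_cluster_eic_peaks <- function(eics, shape_corr_min = 0.8,
                                         rt_tol = 5) {
  peaks <- lapply(eics, detect_eic_peak)
  keep <- !vapply(peaks, is.null, TRUE)
  eics <- eics[keep]; peaks <- peaks[keep]
  if (!length(eics)) return(list())
  ord <- order(-vapply(peaks, `[[`, 1.0, "apex_intensity"))
  clusters <- list()
  for (i in ord) {
    placed <- FALSE
    for (c in seq_along(clusters)) {
      cl <- clusters[[c]]
      seed <- cl$members[[1]]
      if (abs(peaks[[i]]$apex_rt - cl$apex_rt) <= rt_tol) {
        corr <- suppressWarnings(stats::cor(seed$trace, eics[[i]]$intensity))
        if (is.finite(corr) && corr >= shape_corr_min) {
          clusters[[c]]$members[[length(cl$members) + 1L]] <- list(
            eic = eics[[i]], peak = peaks[[i]], trace = eics[[i]]$intensity)
          clusters[[c]]$eic_index <- c(cl$eic_index, i)
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <- list(
        members = list(list(eic = eics[[i]], peak = peaks[[i]],
                            trace = eics[[i]]$intensity)),
        eic_index = i, apex_rt = peaks[[i]]$apex_rt, model_peak = 1L)
    }
  }
  # model peak: highest apex intensity (members were added in intensity
  # order, so it is the first) -- recorded explicitly for clarity
  for (c in seq_along(clusters)) {
    ints <- vapply(clusters[[c]]$members, function(m) m$peak$apex_intensity, 1.0)
    clusters[[c]]$model_peak <- which.max(ints)
  }
  attr(clusters, "eics") <- eics
  clusters
}

#' Decompose every EIC over the cluster model peaks
#'
#' Each EIC trace is fit as a non-negative combination of the model-peak
#' traces (all EICs share the scan grid, so no resampling is needed); the
#' fit reuses the package's non-negative coordinate-descent solver with zero
#' penalty. Weights and per-EIC residuals are returned.
#'
#' @param eics list of EICs (as stored on the cluster attribute).
#' @param clusters list of clusters from [detect_and_cluster_eic_peaks()].
#' @return list with `weights` (matrix, EIC x cluster) and `residual`
#'   (per-EIC RSS).
#' @export
decompose_eics <- function(eics, clusters) {
  if (!length(clusters)) stop("no clusters to decompose against")
  M <- vapply(clusters, function(cl) cl$members[[cl$model_peak]]$trace,
              numeric(length(eics[[1]]$rt)))
  M <- as.matrix(M)
  nrm <- sqrt(colSums(M^2)); nrm[nrm == 0] <- 1
  Mn <- sweep(M, 2, nrm, "/")
  W <- matrix(0, length(eics), length(clusters))
  resid <- numeric(length(eics))
  for (i in seq_along(eics)) {
    y <- eics[[i]]$intensity
    prob <- structure(list(y = y, X = Mn, axis = seq_along(y),
                           penalty_factors = rep(1, ncol(Mn)),
                           col_scale = nrm, provenance = rep("MODEL", ncol(Mn)),
                           ion_mz = rep(NA_real_, ncol(Mn)), main_col = 1L),
                      class = "ms2_deconv_problem")
    sol <- solve_elastic_net(prob, alpha = 0, lambda = 0)
    w <- sol$beta / nrm
    W[i, ] <- w
    resid[i] <- sol$residue
  }
  list(weights = W, residual = resid)
}

#' Reconstruct the pseudo-MS2 spectrum of a feature
#'
#' The target cluster is the one whose apex RT is nearest the feature's
#' `rt_med` (within `rt_tol`); each fragment's pseudo-MS2 intensity is its
#' decomposition weight on the target cluster times the model-peak apex
#' intensity. Zero-weight fragments are omitted and the result normalized.
#'
#' @param feature one row of an `ms1_features` table.
#' @param eics list of EICs.
#' @param clusters clusters from [detect_and_cluster_eic_peaks()].
#' @param decomposition result of [decompose_eics()].
#' @param rt_tol maximum apex-to-feature RT distance (s).
#' @param intensity_floor fragments below this fraction of the pseudo-MS2
#'   base peak are dropped (suppresses numerically tiny weights arising
#'   from chromatographic tail overlap).
#' @return list `(spectrum, flagged)`; `flagged = TRUE` with an empty
#'   spectrum when no cluster co-elutes with the feature.
#' @export
reconstruct_pseudo_ms2 <- function(feature, eics, clusters, decomposition,
                                   rt_tol = 10, intensity_floor = 0.01) {
  if (!length(clusters)) {
    return(list(spectrum = spectrum(numeric(0), numeric(0),
                                    precursor_mz = feature$mz_med,
                                    precursor_rt = feature$rt_med),
                flagged = TRUE))
  }
  apexes <- vapply(clusters, `[[`, 1.0, "apex_rt")
  tgt <- which.min(abs(apexes - feature$rt_med))
  if (abs(apexes[tgt] - feature$rt_med) > rt_tol) {
    return(list(spectrum = spectrum(numeric(0), numeric(0),
                                    precursor_mz = feature$mz_med,
                                    precursor_rt = feature$rt_med),
                flagged = TRUE))
  }
  model_apex <- clusters[[tgt]]$members[[clusters[[tgt]]$model_peak]]$peak$apex_intensity
  w <- decomposition$weights[, tgt]
  frag_mz <- vapply(eics, `[[`, 1.0, "fragment_mz")
  keep <- w * model_apex >= intensity_floor * max(w * model_apex)
  keep <- keep & w > 0
  if (!any(keep)) {
    return(list(spectrum = spectrum(numeric(0), numeric(0),
                                    precursor_mz = feature$mz_med,
                                    precursor_rt = feature$rt_med),
                flagged = TRUE))
  }
  sp <- spectrum(frag_mz[keep], w[keep] * model_apex,
                 precursor_mz = feature$mz_med, precursor_rt = feature$rt_med,
                 source_id = feature$feature_id)
  list(spectrum = normalize_spectrum(sp), flagged = FALSE)
}

#' Deconvolve one DIA feature end to end
#'
#' Runs EIC extraction, peak detection and clustering, model-peak
#' decomposition, and pseudo-MS2 reconstruction.
#'
#' @param feature one row of an `ms1_features` table.
#' @param run an `ms2_run` with DIA scans.
#' @param mz_tol fragment binning tolerance (Th).
#' @param shape_corr_min,rt_tol clustering parameters.
#' @param rt_pad EIC extraction padding (s).
#' @return list `(spectrum, flagged, clusters, decomposition)`.
#' @export
deconvolve_dia <- function(feature, run, mz_tol = 0.01, shape_corr_min = 0.8,
                           rt_tol = 5, rt_pad = 15) {
  eics <- extract_ms2_eics(run, feature, mz_tol, rt_pad)
  if (!length(eics)) {
    return(list(spectrum = spectrum(numeric(0), numeric(0),
                                    precursor_mz = feature$mz_med,
                                    precursor_rt = feature$rt_med),
                flagged = TRUE, clusters = list(), decomposition = NULL))
  }
  clusters <- detect_and_cluster_eic_peaks(eics, shape_corr_min, rt_tol)
  kept_eics <- attr(clusters, "eics")
  if (!length(clusters)) {
    return(list(spectrum = spectrum(numeric(0), numeric(0),
                                    precursor_mz = feature$mz_med,
                                    precursor_rt = feature$rt_med),
                flagged = TRUE, clusters = clusters, decomposition = NULL))
  }
  dec <- decompose_eics(kept_eics, clusters)
  rec <- reconstruct_pseudo_ms2(feature, kept_eics, clusters, dec,
                                rt_tol = 2 * rt_tol)
  list(spectrum = rec$spectrum, flagged = rec$flagged, clusters = clusters,
       decomposition = dec)
}
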