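# Decoy acquisitions for null evaluation. MS1 centroids (and DIA MS2
# fragments) get a random mass error of 10-30 ppm (random sign) and a
# random intensity distortion factor in [0.01, 50]; retention times and
# SWATH windows are untouched. DDA MS2 spectra are replaced by the jittered
# spectrum of a library compound isobaric with the precursor but with a
# different InChIKey; when no such compound exists the scan is perturbed
# like an MS1 scan instead.

perturb_peaks <- function(mz, intensity) {
  n <- length(mz)
  if (!n) return(list(mz = mz, intensity = intensity))
  ppm_err <- stats::runif(n, 10, 30) * sample(c(-1, 1), n, replace = TRUE)
  coefs <- stats::runif(n, 0.01, 50.0)
  list(mz = mz * (1 + ppm_err * 1e-6), intensity = intensity * coefs)
}

#' Generate one decoy run
#'
#' @param run the source `ms2_run`.
#' @param library an open `ms2_library` (needed in DDA mode to source
#'   isobaric replacement spectra).
#' @param mode `"dda"` or `"dia"`.
#' @param seed integer seed; the same seed reproduces the decoy exactly.
#' @param ppm_tol isobaric-match tolerance (ppm) for DDA replacements.
#' @param truth optional named character vector mapping MS2 `source_id` to
#'   the original InChIKey (used to force a different replacement compound).
#' @return a decoy `ms2_run`; RT vectors and (DIA) window indices identical
#'   to the source.
#' @export
generate_decoy_run <- function(run, library = NULL, mode = c("dda", "dia"),
                               seed = 1L, ppm_tol = 10, truth = NULL) {
  mode <- match.arg(mode)
  set.seed(seed)
  ms1 <- lapply(run$ms1, function(s) {
    p <- perturb_peaks(s$mz, s$intensity)
    o <- order(p$mz)
    s$mz <- p$mz[o]; s$intensity <- p$intensity[o]
    s
  })
  ms2 <- lapply(run$ms2, function(s) {
    if (mode == "dia") {
      p <- perturb_peaks(s$mz, s$intensity)
      o <- order(p$mz)
      s$mz <- p$mz[o]; s$intensity <- p$intensity[o]
      return(s)
    }
    # DDA: replace with a jittered isobaric library spectrum
    repl <- NULL
    if (!is.null(library)) {
      recs <- query_by_precursor(library, s$precursor_mz, ppm_tol)
      if (!is.null(truth) && s$source_id %in% names(truth)) {
        recs <- recs[vapply(recs, `[[`, "", "inchikey") != truth[[s$source_id]]]
      }
      if (length(recs)) repl <- recs[[sample.int(length(recs), 1L)]]
    }
    if (is.null(repl)) {
      p <- perturb_peaks(s$mz, s$intensity)
      o <- order(p$mz)
      s$mz <- p$mz[o]; s$intensity <- p$intensity[o]
      message("no isobaric library compound for precursor ",
              round(s$precursor_mz, 4), "; perturbed in place")
      return(s)
    }
    rs <- repl$spectrum
    jitter <- stats::runif(length(rs$mz), 0.5, 2)
    s$mz <- rs$mz
    s$intensity <- rs$intensity * jitter
    s <- tryCatch(normalize_spectrum(s), error = function(e) s)
    s
  })
  ms_run(ms1, ms2)
}

#' Generate a set of decoy runs
#'
#' `n_decoys` independent decoys (default 18 per replicate) with seeds
#' `base_seed + 1 ... base_seed + n_decoys`.
#'
#' @inheritParams generate_decoy_run
#' @param n_decoys number of decoy runs.
#' @param base_seed base seed.
#' @return list of decoy `ms2_run`.
#' @export
generate_decoy_set <- function(run, library = NULL, mode = "dda",
                               n_decoys = 18, base_seed = 1L, ppm_tol = 10,
                               truth = NULL) {
  stopifnot(n_decoys >= 1)
  lapply(seq_len(n_decoys), function(k) {
    generate_decoy_run(run, library, mode, seed = base_seed + k, ppm_tol,
                       truth = truth)
  })
}

#' Null evaluation of decoy search results
#'
#' Every decoy query is a true negative by construction; a top hit whose
#' InChIKey equals the original (pre-perturbation) identity is a false
#' positive. Reports per-run and pooled false-positive rates and a
#' per-score-bin FPR curve.
#'
#' @param decoy_results list of `ms2_match_table` result tables, one per
#'   decoy run (all queries, ranked).
#' @param truth named character vector: `query_id` -> original InChIKey.
#' @param score_bins breaks for the per-score-bin curve.
#' @return list with `per_run` (data frame run, n, fp, fpr), `pooled_fpr`,
#'   and `score_curve`.
#' @export
evaluate_null <- function(decoy_results, truth,
                          score_bins = seq(0, 100, by = 10)) {
  per_run <- data.frame(run = integer(0), n = integer(0), fp = integer(0),
                        fpr = numeric(0))
  top_scores <- numeric(0); top_fp <- logical(0)
  total_q <- 0L; total_fp <- 0L
  for (k in seq_along(decoy_results)) {
    res <- as.data.frame(decoy_results[[k]])
    qids <- unique(res$query_id)
    missing <- setdiff(qids, names(truth))
    if (length(missing)) {
      stop("query ids missing from truth: ", paste(missing, collapse = ", "))
    }
    n_q <- length(names(truth))
    fp <- 0L
    for (q in qids) {
      g <- res[res$query_id == q, , drop = FALSE]
      if (!nrow(g)) next
      top <- g[which.max(g$matching_score), , drop = FALSE]
      is_fp <- identical(top$inchikey, truth[[q]])
      fp <- fp + is_fp
      top_scores <- c(top_scores, top$matching_score)
      top_fp <- c(top_fp, is_fp)
    }
    per_run <- rbind(per_run, data.frame(run = k, n = n_q, fp = fp,
                                         fpr = fp / n_q))
    total_q <- total_q + n_q; total_fp <- total_fp + fp
  }
  bins <- cut(top_scores, score_bins, include.lowest = TRUE)
  curve <- data.frame(bin = levels(bins),
                      n = as.integer(table(bins)),
                      fp = as.integer(tapply(top_fp, bins, sum, default = 0L)))
  curve$fpr <- ifelse(curve$n > 0, curve$fp / curve$n, NA_real_)
  list(per_run = per_run,
       pooled_fpr = if (total_q > 0) total_fp / total_q else NA_real_,
       score_curve = curve)
}
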