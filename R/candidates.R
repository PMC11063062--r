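# Candidate reference spectra for the ions co-isolated with a main ion.
# Resolution order per contamination ion:
#   I   predicted orphan-isotopologue spectrum (parent found in the MS1 scan)
#   II  clean MS2 spectrum of the same ion elsewhere in the data
#   III best-matching library spectrum at the contaminant's precursor m/z
#   IV  transformation-network predicted spectrum (penalized)
# An ion that resolves to none of these is dropped from the regression.

new_candidate <- function(ion_mz, spec, provenance, similarity = NA_real_) {
  penalty <- if (identical(provenance, "IV")) 10 * (1 - similarity) else 0
  structure(list(ion_mz = ion_mz, spectrum = spec, provenance = provenance,
                 similarity_to_spectrum0 = similarity, penalty = penalty),
            class = "ms2_candidate")
}

#' @export
print.ms2_candidate <- function(x, ...) {
  cat(sprintf("<ms2_candidate> class %s, ion %.4f Th, %d fragments, penalty %.2f\n",
              x$provenance, x$ion_mz, length(x$spectrum$mz), x$penalty))
  invisible(x)
}

#' Detect whether a contaminant is an orphan isotopologue
#'
#' Looks in the nearest MS1 scan for a parent centroid at
#' `mz - n * 1.003355 / z` (n in 1:2, z up to `charge_max`) whose intensity
#' is at least the contaminant's. Returns the first parent found, scanning
#' n = 1 before n = 2 and low charges first.
#'
#' @param contaminant numeric `c(mz, intensity)`.
#' @param ms1_scan the nearest MS1 `ms2_spectrum`.
#' @param charge_max maximum charge considered.
#' @param ppm_tol match tolerance in ppm.
#' @return list `(parent_mz, parent_intensity, n, z)` or `NULL`.
#' @export
detect_orphan_isotopologue <- function(contaminant, ms1_scan, charge_max = 2,
                                       ppm_tol = 10) {
  mz <- contaminant[[1]]; int <- contaminant[[2]]
  for (n in 1:2) {
    for (z in seq_len(charge_max)) {
      target <- mz - n * NEUTRON_SHIFT / z
      if (target <= 0) next
      d <- abs(ppm_deviation(ms1_scan$mz, target))
      hit <- which(d <= ppm_tol & ms1_scan$intensity >= int)
      if (length(hit)) {
        hit <- hit[which.min(d[hit])]
        return(list(parent_mz = ms1_scan$mz[hit],
                    parent_intensity = ms1_scan$intensity[hit],
                    n = n, z = z))
      }
    }
  }
  NULL
}

#' Predict the MS2 spectrum of an orphan isotopologue
#'
#' Each parent fragment splits into an unshifted peak and a peak shifted by
#' `n * 1.003355 / z`. The shifted fraction is the probability that the
#' heavy isotope is retained in the fragment: the carbon-count ratio
#' `n_C(fragment) / n_C(precursor)` when formulas are available, else the
#' m/z ratio `fragment_mz / precursor_mz` as a fallback approximation.
#'
#' @param parent_spectrum the parent ion's MS2 `ms2_spectrum`.
#' @param parent_formula optional precursor formula for carbon-count ratios.
#' @param n isotope index (1 or 2).
#' @param z charge.
#' @return normalized predicted `ms2_spectrum`.
#' @export
predict_isotopologue_spectrum <- function(parent_spectrum, parent_formula = NULL,
                                          n = 1, z = 1) {
  if (!n %in% c(1, 2)) stop("isotope index n must be 1 or 2")
  s <- parent_spectrum
  if (!length(s$mz)) stop("empty parent spectrum")
  nC_prec <- if (!is.null(parent_formula)) {
    cnt <- parse_formula(parent_formula)
    if ("C" %in% names(cnt)) cnt[["C"]] else 0L
  } else NA_integer_
  frac <- vapply(seq_along(s$mz), function(i) {
    if (!is.null(s$formulas) && !is.na(s$formulas[i]) &&
        !is.na(nC_prec) && nC_prec > 0) {
      cnt <- parse_formula(s$formulas[i])
      nc <- if ("C" %in% names(cnt)) cnt[["C"]] else 0L
      min(1, nc / nC_prec)
    } else if (is.finite(s$precursor_mz) && s$precursor_mz > 0) {
      min(1, s$mz[i] / s$precursor_mz)
    } else 1
  }, 1.0)
  shift <- n * NEUTRON_SHIFT / z
  mz_all <- c(s$mz, s$mz + shift)
  int_all <- c(s$intensity * (1 - frac), s$intensity * frac)
  keep <- int_all > 0
  out <- spectrum(mz_all[keep], int_all[keep],
                  precursor_mz = if (is.finite(s$precursor_mz))
                    s$precursor_mz + shift else NA_real_,
                  precursor_rt = s$precursor_rt, polarity = s$polarity,
                  source_id = paste0(s$source_id, "+", n, "n/z", z))
  normalize_spectrum(out)
}

#' Find a clean in-data spectrum for a contaminant ion
#'
#' Searches the DDA MS2 scans whose precursor matches `contaminant_mz`
#' within `ppm_tol` and whose RT is within `rt_cap` of `rt`; the two nearest
#' in RT are assessed for chimerism and the nearer clean one is returned
#' normalized.
#'
#' @param contaminant_mz contaminant precursor m/z.
#' @param run the `ms2_run`.
#' @param rt RT (s) of the chimeric scan.
#' @param ppm_tol precursor match tolerance (ppm).
#' @param rt_cap maximum RT distance (s) for a scan to count as "nearby".
#' @param intensity_threshold passed to the cleanliness assessment.
#' @return a normalized clean `ms2_spectrum`, or `NULL`.
#' @export
find_in_data_clean_spectrum <- function(contaminant_mz, run, rt, ppm_tol = 10,
                                        rt_cap = 30, intensity_threshold = 1e4) {
  if (!length(run$ms2)) return(NULL)
  pmz <- vapply(run$ms2, `[[`, 1.0, "precursor_mz")
  prt <- vapply(run$ms2, `[[`, 1.0, "precursor_rt")
  cand <- which(abs(ppm_deviation(pmz, contaminant_mz)) <= ppm_tol &
                  abs(prt - rt) <= rt_cap)
  if (!length(cand)) return(NULL)
  cand <- cand[order(abs(prt[cand] - rt))]
  cand <- cand[seq_len(min(2L, length(cand)))]
  for (k in cand) {
    s <- run$ms2[[k]]
    if (!length(s$mz)) next
    feat <- ms1_features(mz_med = s$precursor_mz, rt_med = s$precursor_rt,
                         intensity = 0)[1, ]
    a <- tryCatch(suppressWarnings(
      assess_chimeric(feat, s, run, intensity_threshold = intensity_threshold)),
      error = function(e) NULL)
    if (!is.null(a) && !a$is_chimeric) return(normalize_spectrum(s))
  }
  NULL
}

#' Select the best library spectrum for a contaminant ion
#'
#' Among library records within `ppm_tol` of the contaminant precursor, the
#' spectrum most similar to the chimeric Spectrum 0 is retained; ties break
#' to the lower record_id (the precursor query returns records in record_id
#' order and the strict maximum keeps the first).
#'
#' @param contaminant_mz contaminant precursor m/z.
#' @param library an open `ms2_library`.
#' @param spectrum0 the chimeric spectrum.
#' @param ppm_tol precursor tolerance (ppm).
#' @param similarity `"dot_product"` or `"spectral_entropy"`.
#' @param polarity optional polarity filter.
#' @return list `(spectrum, record, similarity)` or `NULL`.
#' @export
select_library_candidate <- function(contaminant_mz, library, spectrum0,
                                     ppm_tol = 10,
                                     similarity = "dot_product",
                                     polarity = NULL) {
  recs <- query_by_precursor(library, contaminant_mz, ppm_tol, polarity)
  if (!length(recs)) return(NULL)
  sims <- vapply(recs, function(r)
    spectral_similarity(r$spectrum, spectrum0, similarity), 1.0)
  best <- which.max(sims)
  list(spectrum = normalize_spectrum(recs[[best]]$spectrum),
       record = recs[[best]], similarity = sims[best])
}

#' Remove fragments incompatible with a target formula
#'
#' A fragment survives only when its best formula is an element-wise
#' sub-multiset of `target_formula` (no element count exceeded, no new
#' element type). Fragments without a stored formula are annotated through
#' [predict_formula()] restricted to the target's elements; a fragment with
#' no candidate formula is removed. Survivors are normalized. Idempotent and
#' never increases the fragment count.
#'
#' @param s an `ms2_spectrum`, ideally with per-fragment formulas.
#' @param target_formula the precursor formula that fragments must fit.
#' @param ppm_tol formula-annotation tolerance (ppm).
#' @return the cleaned `ms2_spectrum` (possibly empty).
#' @export
clean_neighbor_spectrum <- function(s, target_formula, ppm_tol = 10) {
  target <- parse_formula(target_formula)
  keep <- logical(length(s$mz))
  for (i in seq_along(s$mz)) {
    f <- if (!is.null(s$formulas)) s$formulas[i] else NA_character_
    if (!is.na(f)) {
      keep[i] <- formula_subset(f, target)
    } else {
      el <- function(e, cap) min(cap, if (e %in% names(target)) target[[e]] else 0L)
      pred <- predict_formula(s$mz[i], polarity = s$polarity, ppm_tol = ppm_tol,
                              bounds = list(C = el("C", 40), H = 80,
                                            N = el("N", 10), O = el("O", 20),
                                            P = el("P", 5), S = el("S", 5)))
      keep[i] <- nrow(pred) > 0 && formula_subset(pred$formula[1], target)
    }
  }
  out <- s
  out$mz <- s$mz[keep]; out$intensity <- s$intensity[keep]
  if (!is.null(s$formulas)) out$formulas <- s$formulas[keep]
  if (length(out$mz)) out <- normalize_spectrum(out)
  out
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Predict the spectrum of an unknown ion via its transformation network
#'
#' The top formula for the unknown precursor is predicted; a one-hop
#' abiotic/biotransformation network is built around it; each neighbor's
#' library spectra are cleaned against the unknown's formula and scored
#' against Spectrum 0; the maximizer is returned as a class-IV candidate
#' with penalty `10 * (1 - similarity)`.
#'
#' @param contaminant_mz unknown ion m/z.
#' @param library an open `ms2_library`.
#' @param spectrum0 the chimeric spectrum.
#' @param ppm_tol formula/precursor tolerance (ppm).
#' @param similarity similarity method name.
#' @param rules transformation rule table.
#' @param polarity ionization polarity of the unknown.
#' @return an `ms2_candidate` of provenance `"IV"`, or `NULL`.
#' @export
predict_unknown_spectrum <- function(contaminant_mz, library, spectrum0,
                                     ppm_tol = 10, similarity = "dot_product",
                                     rules = transformation_rules(),
                                     polarity = "positive") {
  pred <- predict_formula(contaminant_mz, polarity = polarity, ppm_tol = ppm_tol)
  if (!nrow(pred)) return(NULL)
  target <- pred$formula[1]
  net <- build_transformation_network(target, rules)
  if (!nrow(net$neighbors)) return(NULL)
  best <- NULL; best_sim <- -Inf
  for (nf in net$neighbors$formula) {
    recs <- query_by_formula(library, nf)
    for (r in recs) {
      cleaned <- clean_neighbor_spectrum(r$spectrum, target, ppm_tol)
      if (!length(cleaned$mz)) next
      sim <- spectral_similarity(cleaned, spectrum0, similarity)
      if (sim > best_sim) { best_sim <- sim; best <- cleaned }
    }
  }
  if (is.null(best)) return(NULL)
  new_candidate(contaminant_mz, best, "IV", similarity = best_sim)
}

#' Assemble candidate spectra for every contamination ion
#'
#' Resolution order I -> II -> III -> IV; an ion with no candidate is
#' dropped with a warning. A MAIN candidate is always present: the main
#' ion's best library spectrum when one exists, else Spectrum 0 itself.
#'
#' @param assessment a `chimera_assessment`.
#' @param run the `ms2_run`.
#' @param library an open `ms2_library` (or `NULL` to skip classes III/IV).
#' @param ppm_tol precursor/formula tolerance (ppm).
#' @param similarity similarity method name.
#' @param rt_cap RT window (s) for class-II in-data searches.
#' @param intensity_threshold acquisition threshold for cleanliness checks.
#' @return list of `ms2_candidate` (MAIN first).
#' @export
assemble_candidates <- function(assessment, run, library = NULL, ppm_tol = 10,
                                similarity = "dot_product", rt_cap = 30,
                                intensity_threshold = 1e4) {
  s0 <- normalize_spectrum(assessment$spectrum0)
  pol <- s0$polarity
  main_mz <- assessment$main_ion[["mz"]]
  main_cand <- NULL
  if (!is.null(library)) {
    lib_main <- select_library_candidate(main_mz, library, s0, ppm_tol,
                                         similarity, polarity = pol)
    if (!is.null(lib_main)) {
      main_cand <- new_candidate(main_mz, lib_main$spectrum, "MAIN",
                                 similarity = lib_main$similarity)
    }
  }
  if (is.null(main_cand)) main_cand <- new_candidate(main_mz, s0, "MAIN")
  out <- list(main_cand)
  contam <- assessment$contamination_ions
  for (i in seq_len(nrow(contam))) {
    ion <- contam[i, ]
    cand <- NULL
    orphan <- detect_orphan_isotopologue(ion, assessment$nearest_ms1,
                                         ppm_tol = ppm_tol)
    if (!is.null(orphan)) {
      parent_sp <- find_in_data_clean_spectrum(orphan$parent_mz, run,
                                               s0$precursor_rt %||% assessment$nearest_ms1_rt,
                                               ppm_tol, rt_cap,
                                               intensity_threshold)
      if (is.null(parent_sp) && !is.null(library)) {
        lb <- select_library_candidate(orphan$parent_mz, library, s0, ppm_tol,
                                       similarity, polarity = pol)
        if (!is.null(lb)) parent_sp <- lb$spectrum
      }
      if (!is.null(parent_sp)) {
        pred <- predict_isotopologue_spectrum(parent_sp, n = orphan$n,
                                              z = orphan$z)
        cand <- new_candidate(ion[["mz"]], pred, "I")
      }
    }
    if (is.null(cand)) {
      sp <- find_in_data_clean_spectrum(ion[["mz"]], run,
                                        s0$precursor_rt %||% assessment$nearest_ms1_rt,
                                        ppm_tol, rt_cap, intensity_threshold)
      if (!is.null(sp)) cand <- new_candidate(ion[["mz"]], sp, "II")
    }
    if (is.null(cand) && !is.null(library)) {
      lb <- select_library_candidate(ion[["mz"]], library, s0, ppm_tol,
                                     similarity, polarity = pol)
      if (!is.null(lb)) {
        cand <- new_candidate(ion[["mz"]], lb$spectrum, "III",
                              similarity = lb$similarity)
      }
    }
    if (is.null(cand) && !is.null(library)) {
      cand <- predict_unknown_spectrum(ion[["mz"]], library, s0, ppm_tol,
                                       similarity, polarity = pol)
    }
    if (is.null(cand)) {
      warning(sprintf("no candidate spectrum for contamination ion %.4f Th; dropped",
                      ion[["mz"]]), call. = FALSE)
    } else {
      out[[length(out) + 1L]] <- cand
    }
  }
  out
}
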