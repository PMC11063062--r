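# Reference-library searching: composite-score ranking of precursor-matched
# records, neutral-loss fallback through the transformation network, and
# deduplicated result export.

#' Search options
#'
#' @param ppm_tol precursor tolerance (ppm).
#' @param rt_enabled use retention-time similarity (denominator 3.5) or not
#'   (denominator 2.5, the default).
#' @param rt_tol RT tolerance (s) for the exponential RT kernel.
#' @param ms1_tol_ppm tolerance (ppm) for the exponential MS1 kernel.
#' @param similarity_method `"dot_product"` or `"spectral_entropy"`.
#' @param mz_tol fragment alignment tolerance (Th).
#' @param top_n candidates exported per query.
#' @param nl_fallback_threshold score below which neutral-loss searching is
#'   triggered (default 10 of 100).
#' @param isotope_missing `"zero"` scores a missing observed isotope pattern
#'   as 0; `"drop"` removes the term and renormalizes the denominator.
#' @param instrument_type,collision_energy optional exact library filters.
#' @return a list of class `ms2_search_options`.
#' @export
search_options <- function(ppm_tol = 10, rt_enabled = FALSE, rt_tol = 30,
                           ms1_tol_ppm = 10,
                           similarity_method = c("dot_product", "spectral_entropy"),
                           mz_tol = 0.01, top_n = 5,
                           nl_fallback_threshold = 10,
                           isotope_missing = c("zero", "drop"),
                           instrument_type = NULL, collision_energy = NULL) {
  stopifnot(top_n >= 1, nl_fallback_threshold >= 0, nl_fallback_threshold <= 100)
  structure(list(ppm_tol = ppm_tol, rt_enabled = rt_enabled, rt_tol = rt_tol,
                 ms1_tol_ppm = ms1_tol_ppm,
                 similarity_method = match.arg(similarity_method),
                 mz_tol = mz_tol, top_n = top_n,
                 nl_fallback_threshold = nl_fallback_threshold,
                 isotope_missing = match.arg(isotope_missing),
                 instrument_type = instrument_type,
                 collision_energy = collision_energy),
            class = "ms2_search_options")
}

score_record <- function(query, record, observed_isotope, options,
                         query_rt = NULL) {
  ms2 <- spectral_similarity(query, record$spectrum, options$similarity_method,
                             options$mz_tol)
  ms1 <- deviation_similarity(
    ppm_deviation(query$precursor_mz, record$precursor_mz),
    options$ms1_tol_ppm)
  rt <- NULL
  if (options$rt_enabled) {
    qrt <- if (!is.null(query_rt)) query_rt else query$precursor_rt
    lib_rt <- record$rt  # optional record field; absent from the base schema
    rt <- if (!is.null(lib_rt) && is.finite(lib_rt) && is.finite(qrt)) {
      deviation_similarity(qrt - lib_rt, options$rt_tol)
    } else 0
  }
  iso_missing <- is.null(observed_isotope) || all(is.na(observed_isotope))
  iso <- if (iso_missing) 0 else
    isotope_similarity(observed_isotope, record$formula)
  score <- if (iso_missing && options$isotope_missing == "drop") {
    if (options$rt_enabled) (ms2 + ms1 + rt) / 3 * 100 else (ms2 + ms1) / 2 * 100
  } else {
    matching_score(ms2, ms1, rt, iso)
  }
  list(ms2 = ms2, ms1 = ms1, rt = if (is.null(rt)) NA_real_ else rt,
       isotope = iso, score = score)
}

#' Search a query spectrum against a reference library
#'
#' Candidate records are those within `ppm_tol` of the query precursor
#' (passing any instrument/collision-energy filters); each is scored with
#' the composite matching score and results are returned sorted by
#' descending score, ties to the lower record_id.
#'
#' @param query an `ms2_spectrum` with `precursor_mz` set.
#' @param library an open `ms2_library`.
#' @param options an `ms2_search_options`.
#' @param observed_isotope optional observed `c(M1, M2)` fractions.
#' @param query_rt optional query RT (s) overriding the spectrum slot.
#' @param query_id identifier written into results.
#' @return data frame of matches (class `ms2_match_table`) with the four
#'   similarity components, `matching_score` and `match_kind`.
#' @export
search_library <- function(query, library, options = search_options(),
                           observed_isotope = NULL, query_rt = NULL,
                           query_id = query$source_id) {
  if (!is.finite(query$precursor_mz)) stop("query needs a precursor m/z")
  recs <- query_by_precursor(library, query$precursor_mz, options$ppm_tol,
                             instrument_type = options$instrument_type,
                             collision_energy = options$collision_energy)
  rows <- lapply(recs, function(r) {
    sc <- score_record(query, r, observed_isotope, options, query_rt)
    data.frame(query_id = if (is.null(query_id) || is.na(query_id)) "query" else query_id,
               record_id = r$record_id, compound_name = r$compound_name,
               formula = r$formula, inchikey = r$inchikey,
               adduct = r$adduct, matching_score = sc$score,
               ms2_sim = sc$ms2, ms1_sim = sc$ms1, rt_sim = sc$rt,
               isotope_sim = sc$isotope, match_kind = "standard",
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else empty_match_table()
  out <- out[order(-out$matching_score, out$record_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ms2_match_table", "data.frame")
  out
}

empty_match_table <- function() {
  data.frame(query_id = character(0), record_id = integer(0),
             compound_name = character(0), formula = character(0),
             inchikey = character(0), adduct = character(0),
             matching_score = numeric(0), ms2_sim = numeric(0),
             ms1_sim = numeric(0), rt_sim = numeric(0),
             isotope_sim = numeric(0), match_kind = character(0),
             stringsAsFactors = FALSE)
}

#' Neutral-loss fallback search
#'
#' Intended for queries whose best standard score falls below
#' `nl_fallback_threshold` (default 10/100). The query precursor's formula
#' is predicted and a one-hop transformation network built around it; the
#' neighbors' formulas define the targets extracted from the neutral-loss
#' library, and the query's neutral-loss spectrum is scored against them
#' with the same composite scoring. Results carry
#' `match_kind = "neutral_loss"`.
#'
#' @param query an `ms2_spectrum` with precursor set.
#' @param nl_library an open `ms2_library` holding neutral-loss spectra
#'   (see [derive_neutral_loss_library()]).
#' @param options an `ms2_search_options`.
#' @param best_standard_score the best score from the standard search; the
#'   fallback runs only when it is below the threshold unless
#'   `force = TRUE`.
#' @param force run regardless of the threshold.
#' @param rules transformation rule table.
#' @param query_id identifier written into results.
#' @return an `ms2_match_table` (possibly empty).
#' @export
neutral_loss_search <- function(query, nl_library, options = search_options(),
                                best_standard_score = 0, force = FALSE,
                                rules = transformation_rules(),
                                query_id = query$source_id) {
  if (!force && best_standard_score >= options$nl_fallback_threshold) {
    return(empty_match_table())
  }
  pred <- predict_formula(query$precursor_mz, polarity = query$polarity,
                          ppm_tol = options$ppm_tol)
  if (!nrow(pred)) return(empty_match_table())
  net <- build_transformation_network(pred$formula[1], rules)
  targets <- unique(c(net$center, net$neighbors$formula))
  nl_query <- neutral_loss_spectrum(query)
  rows <- list()
  for (f in targets) {
    for (r in query_by_formula(nl_library, f)) {
      if (!length(r$spectrum$mz)) next
      sc <- score_record(nl_query, r, NULL, options)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = if (is.null(query_id) || is.na(query_id)) "query" else query_id,
        record_id = r$record_id, compound_name = r$compound_name,
        formula = r$formula, inchikey = r$inchikey, adduct = r$adduct,
        matching_score = sc$score, ms2_sim = sc$ms2, ms1_sim = sc$ms1,
        rt_sim = sc$rt, isotope_sim = sc$isotope,
        match_kind = "neutral_loss", stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_match_table()
  out <- out[order(-out$matching_score, out$record_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ms2_match_table", "data.frame")
  out
}

#' Export ranked, deduplicated search results
#'
#' Per query, records sharing an InChIKey keep only the highest-scoring
#' row; the top `top_n` rows per query are written as CSV (and returned).
#'
#' @param matches an `ms2_match_table` (rows from one or more queries).
#' @param top_n rows kept per query.
#' @param path optional output CSV path.
#' @return the exported data frame, invisibly when `path` is given.
#' @export
export_results <- function(matches, top_n = 5, path = NULL) {
  df <- as.data.frame(matches)
  if (nrow(df)) {
    df <- df[order(df$query_id, -df$matching_score, df$record_id), , drop = FALSE]
    dup <- duplicated(df[, c("query_id", "inchikey")])
    df <- df[!dup, , drop = FALSE]
    df <- do.call(rbind, lapply(split(df, df$query_id), function(g) {
      g[seq_len(min(top_n, nrow(g))), , drop = FALSE]
    }))
    rownames(df) <- NULL
  }
  cols <- c("query_id", "compound_name", "formula", "inchikey", "adduct",
            "matching_score", "ms2_sim", "ms1_sim", "rt_sim", "isotope_sim",
            "match_kind")
  df <- df[, cols, drop = FALSE]
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
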