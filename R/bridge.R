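# Bridge from MS2 identifications to pathway-level enrichment tooling:
# per-feature compound ID lists and MS2-aware filtering of
# empirical-compound candidate maps. The enrichment test itself is external.

#' Per-feature compound ID lists for enrichment tools
#'
#' For each query feature with at least one hit, an ordered, deduplicated ID
#' list: InChIKey first, then any KEGG/HMDB IDs supplied through a mapping
#' table. Features without hits are omitted.
#'
#' @param results an `ms2_match_table` / data frame of search results.
#' @param id_mapping optional data frame with columns `inchikey` and any of
#'   `kegg`, `hmdb`.
#' @return named list: `feature_id -> character vector of IDs`.
#' @export
format_for_enrichment <- function(results, id_mapping = NULL) {
  df <- as.data.frame(results)
  if (!nrow(df)) return(list())
  out <- lapply(split(df, df$query_id), function(g) {
    g <- g[order(-g$matching_score), , drop = FALSE]
    keys <- unique(g$inchikey)
    ids <- keys
    if (!is.null(id_mapping)) {
      for (col in intersect(c("kegg", "hmdb"), names(id_mapping))) {
        extra <- id_mapping[[col]][match(keys, id_mapping$inchikey)]
        ids <- c(ids, extra[!is.na(extra)])
      }
    }
    unique(ids)
  })
  out[vapply(out, length, 1L) > 0]
}

inchikey_block1 <- function(k) sub("-.*$", "", k)

#' Filter empirical-compound candidates with MS2 identifications
#'
#' A feature mapped to several candidate compounds keeps only the candidates
#' matching its MS2 identification; features without an MS2 identification
#' are untouched; when no candidate matches, the MS2-identified compound
#' becomes the sole candidate. By default compounds are compared on the
#' first (skeleton) block of the InChIKey so stereo/protonation variants
#' are treated as the same compound; `strict = TRUE` compares full keys.
#' Never increases a feature's candidate count; idempotent.
#'
#' @param ecpds named list: `feature_id -> character vector` of candidate
#'   compound InChIKeys.
#' @param ms2_ids named character vector: `feature_id -> identified
#'   InChIKey`.
#' @param strict compare full InChIKeys instead of the first block.
#' @return the filtered candidate map.
#' @export
filter_empirical_compounds <- function(ecpds, ms2_ids, strict = FALSE) {
  key <- if (strict) identity else inchikey_block1
  out <- ecpds
  for (f in names(ecpds)) {
    if (!f %in% names(ms2_ids) || is.na(ms2_ids[[f]])) next
    id <- ms2_ids[[f]]
    hits <- ecpds[[f]][key(ecpds[[f]]) == key(id)]
    out[[f]] <- if (length(hits)) hits else id
  }
  out
}
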