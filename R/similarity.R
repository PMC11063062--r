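# Spectral similarity metrics and the composite matching score.

#' Dot-product (cosine) spectral similarity
#'
#' Fragments are aligned at `mz_tol`; similarity is the cosine between the
#' square-root-transformed intensity vectors (MS-DIAL convention). Plain
#' intensities are available with `sqrt_transform = FALSE`. Symmetric, in
#' `[0, 1]`, 1 on self-comparison.
#'
#' @param a,b `ms2_spectrum` objects.
#' @param mz_tol alignment tolerance (Th).
#' @param sqrt_transform use square-root intensity weighting (default TRUE).
#' @return similarity in `[0, 1]`.
#' @export
dot_product_similarity <- function(a, b, mz_tol = 0.01, sqrt_transform = TRUE) {
  if (!length(a$mz) || !length(b$mz)) {
    warning("empty spectrum in similarity computation", call. = FALSE)
    return(0)
  }
  al <- align_spectra(list(a, b), mz_tol)
  u <- al$intensity[, 1]; v <- al$intensity[, 2]
  if (sqrt_transform) { u <- sqrt(u); v <- sqrt(v) }
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  min(1, max(0, sum(u * v) / (nu * nv)))
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Spectral-entropy similarity
#'
#' With intensities normalized to probabilities, the similarity of spectra a
#' and b is `1 - (2*S_ab - S_a - S_b) / ln(4)` where `S` is the Shannon
#' entropy and the merged spectrum is the aligned average `(a + b) / 2`.
#' Clipped to `[0, 1]`; symmetric; 1 on self-comparison.
#'
#' @inheritParams dot_product_similarity
#' @return similarity in `[0, 1]`.
#' @export
entropy_similarity <- function(a, b, mz_tol = 0.01) {
  if (!length(a$mz) || !length(b$mz)) {
    warning("empty spectrum in similarity computation", call. = FALSE)
    return(0)
  }
  al <- align_spectra(list(a, b), mz_tol)
  pa <- al$intensity[, 1] / sum(al$intensity[, 1])
  pb <- al$intensity[, 2] / sum(al$intensity[, 2])
  pm <- (pa + pb) / 2
  sim <- 1 - (2 * shannon_entropy(pm) - shannon_entropy(pa) -
                shannon_entropy(pb)) / log(4)
  min(1, max(0, sim))
}

#' Similarity of two spectra by a named method
#'
#' @param a,b `ms2_spectrum` objects.
#' @param method `"dot_product"` or `"spectral_entropy"`.
#' @param mz_tol alignment tolerance (Th).
#' @return similarity in `[0, 1]`.
#' @export
spectral_similarity <- function(a, b, method = c("dot_product", "spectral_entropy"),
                                mz_tol = 0.01) {
  method <- match.arg(method)
  if (method == "dot_product") dot_product_similarity(a, b, mz_tol)
  else entropy_similarity(a, b, mz_tol)
}

#' Exponential deviation similarity
#'
#' Maps an absolute deviation (m/z in ppm, or RT in seconds) and its
#' tolerance to a similarity via `exp(-|delta| / tol)`: 1 at zero deviation,
#' decaying towards 0. Serves both the MS1 and the RT term of the composite
#' score.
#'
#' @param delta observed deviation.
#' @param tol tolerance in the same units; must be > 0.
#' @return similarity in `(0, 1]`.
#' @export
deviation_similarity <- function(delta, tol) {
  if (tol <= 0) stop("tolerance must be positive")
  exp(-abs(delta) / tol)
}

#' Composite matching score
#'
#' `(MS2 + MS1 + RT + 0.5 * Isotope) / 3.5 * 100` with retention time
#' enabled; when RT matching is disabled the RT term is dropped and the
#' denominator becomes 2.5. Each component must lie in `[0, 1]`; the score
#' ranges from 0 (no match) to 100 (perfect match).
#'
#' @param ms2,ms1,isotope component similarities in `[0, 1]`.
#' @param rt RT similarity in `[0, 1]`, or `NULL` when RT matching is
#'   disabled.
#' @return score in `[0, 100]`.
#' @export
matching_score <- function(ms2, ms1, rt = NULL, isotope = 0) {
  comps <- c(ms2, ms1, isotope, rt)
  if (any(comps < 0 | comps > 1)) stop("score components must be in [0, 1]")
  if (is.null(rt)) (ms2 + ms1 + 0.5 * isotope) / 2.5 * 100
  else (ms2 + ms1 + rt + 0.5 * isotope) / 3.5 * 100
}

#' Neutral-loss mirror of a spectrum
#'
#' Every fragment (mz, i) becomes (precursor_mz - mz, i): the neutral-loss
#' ion with the intensity mirrored directly. Losses with non-positive m/z
#' are dropped; the result is sorted ascending. Applying the transform twice
#' restores the original fragment m/z set.
#'
#' @param s an `ms2_spectrum` with `precursor_mz` set.
#' @return the neutral-loss `ms2_spectrum`.
#' @export
neutral_loss_spectrum <- function(s) {
  if (!is.finite(s$precursor_mz)) stop("neutral-loss spectrum needs a precursor m/z")
  nl_mz <- s$precursor_mz - s$mz
  keep <- nl_mz > 0
  spectrum(nl_mz[keep], s$intensity[keep], precursor_mz = s$precursor_mz,
           precursor_rt = s$precursor_rt, polarity = s$polarity,
           source_id = s$source_id)
}
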