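# Theoretical isotope patterns and the isotope-distribution similarity term
# of the composite matching score. Only M+1 and M+2 are modelled: heavier
# isotopologues are too weak and too variable to score reliably.

# natural isotope abundances by nominal mass offset (0, +1, +2), IUPAC values
ISOTOPE_ABUNDANCE <- list(
  C = c(0.9893,   0.0107,   0),
  H = c(0.999885, 0.000115, 0),
  N = c(0.99636,  0.00364,  0),
  O = c(0.99757,  0.00038,  0.00205),
  S = c(0.9499,   0.0075,   0.0425),
  P = c(1, 0, 0)
)

# convolution of two offset-distributions truncated at offset 2
conv3 <- function(a, b) {
  c(a[1] * b[1],
    a[1] * b[2] + a[2] * b[1],
    a[1] * b[3] + a[2] * b[2] + a[3] * b[1])
}

#' Theoretical M+1 / M+2 isotope pattern of a formula
#'
#' Relative abundances of the first two isotopologues as fractions of the
#' monoisotopic peak, from polynomial expansion of the per-element natural
#' isotope distributions (13C, 2H, 15N, 17O/18O, 33S/34S; phosphorus is
#' monoisotopic). Elements outside C, H, N, O, P, S are rejected.
#'
#' @param formula formula string or named count vector.
#' @return numeric vector `c(M1, M2)` of abundances relative to M.
#' @export
theoretical_isotope_pattern <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  counts <- counts[counts > 0]
  bad <- setdiff(names(counts), names(ISOTOPE_ABUNDANCE))
  if (length(bad)) stop("unsupported element for isotope pattern: ",
                        paste(bad, collapse = ", "))
  dist <- c(1, 0, 0)
  for (el in names(counts)) {
    base <- ISOTOPE_ABUNDANCE[[el]]
    # element^n by binary exponentiation on the truncated polynomial
    n <- counts[[el]]
    pw <- base
    acc <- c(1, 0, 0)
    while (n > 0) {
      if (n %% 2 == 1) acc <- conv3(acc, pw)
      pw <- conv3(pw, pw)
      n <- n %/% 2
    }
    dist <- conv3(dist, acc)
  }
  c(M1 = dist[2] / dist[1], M2 = dist[3] / dist[1])
}

#' Isotope-pattern similarity
#'
#' Compares an observed M+1/M+2 pattern (fractions of M) with the theoretical
#' pattern of a formula: `max(0, 1 - sum(|obs - theo|) / sum(theo))`. A
#' missing observed pattern scores 0 by default (conservative); callers may
#' instead drop the isotope term from the composite score.
#'
#' @param observed numeric `c(M1, M2)` observed fractions, or `NULL`.
#' @param formula formula string or count vector.
#' @return similarity in `[0, 1]`.
#' @export
isotope_similarity <- function(observed, formula) {
  if (is.null(observed) || all(is.na(observed))) return(0)
  stopifnot(length(observed) >= 2, all(observed[1:2] >= 0, na.rm = TRUE))
  theo <- theoretical_isotope_pattern(formula)
  denom <- sum(theo)
  if (denom <= 0) return(if (sum(observed[1:2]) == 0) 1 else 0)
  max(0, 1 - sum(abs(observed[1:2] - theo)) / denom)
}
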