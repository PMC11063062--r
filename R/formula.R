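# Elemental formula arithmetic: parsing, monoisotopic mass, bounded CHNOPS
# enumeration for formula prediction, and the one-hop transformation network
# used both for unknown-ion spectrum prediction and neutral-loss searching.

# monoisotopic masses of the elements handled by the pipeline
ELEMENT_MASS <- c(
  C = 12.0, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
  P = 30.97376163, S = 31.97207100, Na = 22.9897692809, Cl = 34.96885268,
  K = 38.96370668, F = 18.99840322
)

PROTON_MASS <- 1.007276466
NEUTRON_SHIFT <- 1.003355  # 13C - 12C mass difference, Da

#' Parse an elemental formula string
#'
#' Accepts Hill-style formulas such as `"C6H12O6"` (two-letter element
#' symbols supported). Returns a named integer vector of element counts.
#'
#' @param formula formula string.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) stop("empty formula")
  s <- gsub("\\s", "", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  toks <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(s)) {
    stop("unparseable formula: ", formula)
  }
  counts <- integer(0)
  for (t in toks) {
    el <- sub("[0-9]*$", "", t)
    n <- sub("^[A-Za-z]+", "", t)
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  counts
}

#' Format element counts as a formula string
#'
#' Hill order (C, H, then alphabetical); zero-count elements dropped.
#'
#' @param counts named integer vector as returned by [parse_formula()].
#' @return formula string.
#' @export
format_formula <- function(counts) {
  counts <- counts[counts != 0]
  if (!length(counts)) return("")
  els <- names(counts)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    if (counts[[e]] == 1L) e else paste0(e, counts[[e]])
  }, ""), collapse = "")
}

#' Monoisotopic mass of a neutral formula
#'
#' @param formula formula string or named count vector.
#' @return mass in Da.
#' @export
formula_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  unknown <- setdiff(names(counts), names(ELEMENT_MASS))
  if (length(unknown)) stop("unsupported element(s): ", paste(unknown, collapse = ", "))
  sum(ELEMENT_MASS[names(counts)] * counts)
}

# common adduct set: name -> list(mass shift applied to neutral M, charge z)
ADDUCTS <- list(
  "[M+H]+"   = list(shift = PROTON_MASS,                      z = 1L, polarity = "positive"),
  "[M+Na]+"  = list(shift = 22.9897692809 - 0.000548579909,   z = 1L, polarity = "positive"),
  "[M+NH4]+" = list(shift = 18.033823,                        z = 1L, polarity = "positive"),
  "[M-H]-"   = list(shift = -PROTON_MASS,                     z = 1L, polarity = "negative"),
  "[M]"      = list(shift = 0,                                z = 0L, polarity = NA_character_)
)

#' m/z of a neutral formula under an adduct
#'
#' @param formula formula string or count vector.
#' @param adduct one of `names(ADDUCTS)`, e.g. `"[M+H]+"`.
#' @return m/z in Th.
#' @export
adduct_mz <- function(formula, adduct = "[M+H]+") {
  a <- ADDUCTS[[adduct]]
  if (is.null(a)) stop("unknown adduct: ", adduct)
  formula_mass(formula) + a$shift
}

#' Predict elemental formulas for an observed m/z
#'
#' Bounded enumeration over C, H, N, O, P, S: for every combination of the
#' heavy elements within bounds, the hydrogen count is solved from the
#' residual mass, so the search is linear in the CNOPS grid rather than the
#' full six-dimensional lattice. Candidates are filtered by
#' ring-plus-double-bond equivalents (RDBE >= 0) and an H/C plausibility
#' window, then ranked by absolute ppm deviation.
#'
#' @param mz observed m/z (Th).
#' @param polarity `"positive"`, `"negative"`, or `"neutral"` (mz taken as
#'   neutral mass).
#' @param adducts character vector of adduct names to consider; ignored for
#'   neutral input.
#' @param ppm_tol matching tolerance in ppm.
#' @param bounds named list of per-element maxima (defaults `C<=40, H<=80,
#'   N<=10, O<=20, P<=5, S<=5`).
#' @return data frame with columns `formula`, `adduct`, `neutral_mass`,
#'   `ppm`, ordered by `|ppm|`; zero rows when nothing matches.
#' @export
predict_formula <- function(mz, polarity = "positive", adducts = NULL,
                            ppm_tol = 5,
                            bounds = list(C = 40, H = 80, N = 10, O = 20,
                                          P = 5, S = 5)) {
  stopifnot(mz > 0)
  if (is.null(adducts)) {
    adducts <- switch(polarity,
      positive = c("[M+H]+", "[M+Na]+", "[M+NH4]+"),
      negative = "[M-H]-",
      neutral = "[M]",
      stop("polarity must be positive, negative or neutral"))
  }
  grid <- expand.grid(C = 0:bounds$C, N = 0:bounds$N, O = 0:bounds$O,
                      P = 0:bounds$P, S = 0:bounds$S)
  base_mass <- grid$C * ELEMENT_MASS[["C"]] + grid$N * ELEMENT_MASS[["N"]] +
    grid$O * ELEMENT_MASS[["O"]] + grid$P * ELEMENT_MASS[["P"]] +
    grid$S * ELEMENT_MASS[["S"]]
  out <- list()
  for (ad in adducts) {
    a <- ADDUCTS[[ad]]
    if (is.null(a)) stop("unknown adduct: ", ad)
    target <- mz - a$shift  # neutral mass implied by this adduct
    tol_da <- target * ppm_tol * 1e-6
    h_exact <- (target - base_mass) / ELEMENT_MASS[["H"]]
    h <- round(h_exact)
    keep <- h >= 0 & h <= bounds$H &
      abs((base_mass + h * ELEMENT_MASS[["H"]]) - target) <= tol_da
    if (!any(keep)) next
    g <- grid[keep, , drop = FALSE]
    hk <- h[keep]
    rdbe <- g$C - hk / 2 + (g$N + g$P) / 2 + 1
    # element-ratio plausibility (common-range heuristics): H/C <= 6,
    # N/C <= 1.3, O/C <= 3 for carbon-containing candidates
    hc_ok <- g$C == 0 | (hk / pmax(g$C, 1) <= 6)
    nc_ok <- g$C == 0 | (g$N / pmax(g$C, 1) <= 1.3)
    oc_ok <- g$C == 0 | (g$O / pmax(g$C, 1) <= 3)
    valid <- rdbe >= 0 & hc_ok & nc_ok & oc_ok &
      (g$C + hk + g$N + g$O + g$P + g$S) > 0
    if (!any(valid)) next
    g <- g[valid, , drop = FALSE]; hk <- hk[valid]
    nm <- base_mass[keep][valid] + hk * ELEMENT_MASS[["H"]]
    fs <- vapply(seq_len(nrow(g)), function(i) {
      format_formula(c(C = g$C[i], H = hk[i], N = g$N[i], O = g$O[i],
                       P = g$P[i], S = g$S[i]))
    }, "")
    out[[ad]] <- data.frame(formula = fs, adduct = ad, neutral_mass = nm,
                            ppm = ppm_deviation(nm + a$shift, mz),
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(formula = character(0), adduct = character(0),
                      neutral_mass = numeric(0), ppm = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(abs(res$ppm)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Default biotransformation rule table
#'
#' A curated set of common abiotic/biotransformation mass deltas
#' (hydrogenation, methylation, oxidation, hydration, amination,
#' (de)carbonylation, (de)carboxylation, acetylation, sulfation,
#' glucuronidation, ethylation, phosphorylation), each applied in both
#' directions. Shipped as an editable tab-separated resource under
#' `inst/extdata/transformation_rules.tsv`.
#'
#' @return data frame with columns `rule`, `delta_formula`, `sign`.
#' @export
transformation_rules <- function() {
  path <- system.file("extdata", "transformation_rules.tsv",
                      package = "ms2deconv")
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' One-hop transformation network around a formula
#'
#' Applies each rule delta in its stated direction; a subtraction that would
#' drive any element count negative is rejected. The network is deliberately
#' not propagated beyond one hop to avoid combinatorial redundancy.
#'
#' @param formula center formula string.
#' @param rules rule table as from [transformation_rules()].
#' @return list with `center` (formula string) and `neighbors` (data frame
#'   `formula`, `rule`, `mass_shift`).
#' @export
build_transformation_network <- function(formula, rules = transformation_rules()) {
  center <- parse_formula(formula)
  nb <- list()
  for (i in seq_len(nrow(rules))) {
    delta <- parse_formula(rules$delta_formula[i])
    sgn <- rules$sign[i]
    els <- union(names(center), names(delta))
    cc <- stats::setNames(rep(0L, length(els)), els)
    cc[names(center)] <- center
    dd <- stats::setNames(rep(0L, length(els)), els)
    dd[names(delta)] <- delta
    res <- cc + sgn * dd
    if (any(res < 0)) next
    if (all(res == 0)) next
    nb[[length(nb) + 1L]] <- data.frame(
      formula = format_formula(res), rule = rules$rule[i],
      mass_shift = sgn * formula_mass(delta), stringsAsFactors = FALSE)
  }
  neighbors <- if (length(nb)) do.call(rbind, nb) else
    data.frame(formula = character(0), rule = character(0),
               mass_shift = numeric(0))
  # identical product via different rules: keep first occurrence
  neighbors <- neighbors[!duplicated(neighbors$formula), , drop = FALSE]
  rownames(neighbors) <- NULL
  list(center = format_formula(center), neighbors = neighbors)
}

#' Is formula `sub` an element-wise sub-multiset of `sup`?
#'
#' Used to discard fragments whose formula requires more atoms of some
#' element, or a new element type, relative to the precursor formula.
#'
#' @param sub,sup formula strings or count vectors.
#' @return logical.
#' @export
formula_subset <- function(sub, sup) {
  a <- if (is.character(sub)) parse_formula(sub) else sub
  b <- if (is.character(sup)) parse_formula(sup) else sup
  a <- a[a > 0]
  if (length(setdiff(names(a), names(b[b > 0])))) return(FALSE)
  all(vapply(names(a), function(e) a[[e]] <= b[[e]], TRUE))
}
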