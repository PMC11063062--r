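# shared fixtures and independent oracles, built in code at test time

sp <- function(mz, intensity, pmz = NA_real_, rt = NA_real_, ...) {
  spectrum(mz, intensity, precursor_mz = pmz, precursor_rt = rt, ...)
}

# build a small SQLite library from plain lists
tiny_library <- function(recs, path = tempfile(fileext = ".sqlite")) {
  records <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    structure(list(
      record_id = if (!is.null(r$record_id)) r$record_id else i,
      compound_name = if (!is.null(r$name)) r$name else paste0("cpd", i),
      formula = if (!is.null(r$formula)) r$formula else "C6H12O6",
      inchikey = if (!is.null(r$inchikey)) r$inchikey else
        sprintf("%s-TESTKEY%02d-N", paste(rep("A", 14), collapse = ""), i),
      precursor_mz = r$precursor_mz, adduct = "[M+H]+",
      polarity = "positive", collision_energy = "30",
      instrument_type = "QTOF",
      spectrum = spectrum(r$mz, r$intensity, precursor_mz = r$precursor_mz,
                          polarity = "positive",
                          formulas = r$fragment_formulas)
    ), class = "ms2_library_record")
  })
  write_library(records, path)
  path
}

# independent isotope-pattern oracle: convolve one atom at a time over an
# untruncated offset vector, then read off offsets 1 and 2
oracle_isotope_pattern <- function(formula) {
  ab <- list(C = c(0.9893, 0.0107), H = c(0.999885, 0.000115),
             N = c(0.99636, 0.00364), O = c(0.99757, 0.00038, 0.00205),
             S = c(0.9499, 0.0075, 0.0425), P = 1)
  counts <- parse_formula(formula)
  dist <- 1
  for (el in names(counts)) {
    for (k in seq_len(counts[[el]])) {
      a <- ab[[el]]
      new <- numeric(length(dist) + length(a) - 1)
      for (i in seq_along(dist)) {
        for (j in seq_along(a)) {
          new[i + j - 1] <- new[i + j - 1] + dist[i] * a[j]
        }
      }
      dist <- new
    }
  }
  c(M1 = if (length(dist) > 1) dist[2] / dist[1] else 0,
    M2 = if (length(dist) > 2) dist[3] / dist[1] else 0)
}

# non-negative least squares oracle (active-set, independent implementation)
oracle_nnls <- function(X, y) pracma::lsqnonneg(X, y)$x

# random CHNOS formula for property tests
random_chnos <- function() {
  format_formula(c(C = sample(1:20, 1), H = sample(1:30, 1),
                   N = sample(0:5, 1), O = sample(0:10, 1),
                   S = sample(0:3, 1)))
}
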