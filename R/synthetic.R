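# Seeded synthetic-data generators: reference libraries with known spectra,
# DDA runs with known chimeric composition, SWATH-DIA runs with known
# co-elution structure, and replicate sets. These are first-class package
# code - the test substrate for every other module - not fixtures on disk.

# deterministic fake InChIKey from an integer id (valid shape, not a real key)
synthetic_inchikey <- function(id) {
  set.seed(id * 7919L)
  blk1 <- paste(sample(LETTERS, 14, replace = TRUE), collapse = "")
  blk2 <- paste(sample(LETTERS, 8, replace = TRUE), collapse = "")
  paste0(blk1, "-", blk2, "SA-N")
}

random_formula <- function() {
  C <- sample(6:20, 1)
  H <- 2 * sample(ceiling(C / 2):(C + 1), 1)
  N <- sample(0:2, 1)
  O <- sample(1:8, 1)
  format_formula(c(C = C, H = H, N = N, O = O))
}

# partner with a nearby-but-distinct [M+H]+ (replace CH4 by O: -36.4 mDa)
partner_formula <- function(formula) {
  cnt <- parse_formula(formula)
  if (cnt[["C"]] < 2 || cnt[["H"]] < 5) return(NULL)
  cnt[["C"]] <- cnt[["C"]] - 1L
  cnt[["H"]] <- cnt[["H"]] - 4L
  cnt[["O"]] <- (if ("O" %in% names(cnt)) cnt[["O"]] else 0L) + 1L
  format_formula(cnt)
}

#' Generate a synthetic SQLite reference library
#'
#' Compounds carry random CHNO formulas, `[M+H]+` precursors consistent
#' with the formula mass, and reproducible random fragment sets (all
#' fragment m/z below the precursor, base peak 100). A fraction of the
#' compounds come in mass-close pairs (a second compound whose precursor
#' lies within ~40 mDa), which makes co-isolation chimeras constructible.
#' Same seed, same file content.
#'
#' @param n_compounds number of records.
#' @param fragments_per_compound integer range `c(min, max)`.
#' @param seed integer seed.
#' @param path output SQLite path.
#' @param paired_fraction fraction of compounds given a mass-close partner
#'   (partners count towards `n_compounds`).
#' @param isomer_fraction fraction of compounds given an isomer: same
#'   formula and precursor m/z, different fragment spectrum and InChIKey
#'   (isomers count towards `n_compounds`). Isomers make the library
#'   realistic for decoy replacement and search-ranking studies.
#' @return invisible list with `path` and `manifest` (data frame record_id,
#'   compound_name, formula, inchikey, precursor_mz, partner_of,
#'   isomer_of).
#' @export
make_synthetic_library <- function(n_compounds, fragments_per_compound = c(4, 10),
                                   seed = 1L, path = tempfile(fileext = ".sqlite"),
                                   paired_fraction = 0, isomer_fraction = 0) {
  stopifnot(n_compounds >= 1)
  set.seed(seed)
  records <- list()
  manifest <- data.frame(record_id = integer(0), compound_name = character(0),
                         formula = character(0), inchikey = character(0),
                         precursor_mz = numeric(0), partner_of = integer(0),
                         isomer_of = integer(0))
  id <- 0L
  n_pairs <- floor(n_compounds * paired_fraction / 2)
  n_isomers <- floor(n_compounds * isomer_fraction / 2)
  make_record <- function(id, formula, partner_of = NA_integer_) {
    pmz <- adduct_mz(formula, "[M+H]+")
    nf <- sample(fragments_per_compound[1]:fragments_per_compound[2], 1)
    fmz <- sort(stats::runif(nf, 50, pmz - 10))
    fint <- stats::runif(nf, 5, 100)
    fint[which.max(fint)] <- 100
    structure(list(
      record_id = id, compound_name = paste0("SYN_CPD_", id),
      formula = formula, inchikey = synthetic_inchikey(id),
      precursor_mz = pmz, adduct = "[M+H]+", polarity = "positive",
      collision_energy = "30", instrument_type = "QTOF",
      spectrum = spectrum(fmz, fint, precursor_mz = pmz,
                          polarity = "positive", source_id = paste0("lib:", id))
    ), class = "ms2_library_record")
  }
  add_row <- function(rec, partner_of = NA_integer_, isomer_of = NA_integer_) {
    manifest <<- rbind(manifest, data.frame(
      record_id = rec$record_id, compound_name = rec$compound_name,
      formula = rec$formula, inchikey = rec$inchikey,
      precursor_mz = rec$precursor_mz, partner_of = partner_of,
      isomer_of = isomer_of))
  }
  done_pairs <- 0L; done_isomers <- 0L
  while (id < n_compounds) {
    id <- id + 1L
    f <- random_formula()
    # base formulas kept unique so per-compound formula lookups are clean
    while (f %in% manifest$formula) f <- random_formula()
    rec <- make_record(id, f)
    records[[id]] <- rec
    add_row(rec)
    base_id <- id
    if (done_pairs < n_pairs && id < n_compounds) {
      pf <- partner_formula(f)
      if (!is.null(pf) && !pf %in% manifest$formula) {
        id <- id + 1L
        prec <- make_record(id, pf)
        records[[id]] <- prec
        add_row(prec, partner_of = base_id)
        done_pairs <- done_pairs + 1L
      }
    }
    if (done_isomers < n_isomers && id < n_compounds) {
      id <- id + 1L
      iso <- make_record(id, f)  # same formula, fresh random spectrum
      iso$compound_name <- paste0("SYN_CPD_", base_id, "_ISO")
      records[[id]] <- iso
      add_row(iso, isomer_of = base_id)
      done_isomers <- done_isomers + 1L
    }
  }
  write_library(records, path)
  invisible(list(path = path, manifest = manifest))
}

gaussian_peak <- function(t, apex_rt, width_sigma) {
  exp(-(t - apex_rt)^2 / (2 * width_sigma^2))
}

lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate DDA replicate runs with known chimeric composition
#'
#' Features are compounds drawn from the library, eluting as Gaussian
#' chromatographic peaks with M+1/M+2 isotope satellites from
#' [theoretical_isotope_pattern()]. A chimeric feature co-elutes with a
#' mass-close partner compound inside its isolation window, and its MS2
#' scan is the mixing-weight-weighted union of the two library spectra plus
#' multiplicative log-normal noise. Ground truth (compound map, mixing
#' weights, clean/chimeric labels) is returned alongside the runs.
#'
#' @param library_path path to a library from [make_synthetic_library()]
#'   (pairs are found via its manifest).
#' @param manifest the generator manifest for the same library.
#' @param n_features number of MS1 features to simulate.
#' @param chimera_fraction fraction of features made chimeric (their count
#'   is `round(n_features * chimera_fraction)`).
#' @param weights_range main-ion mixing weight range `c(lo, hi)`.
#' @param noise_cv multiplicative noise CV on MS2 fragment intensities.
#' @param n_replicates replicate runs generated.
#' @param seed integer seed.
#' @param peak_sigma chromatographic peak sigma (s).
#' @param scan_period MS1 scan period (s).
#' @param isolation_halfwidth isolation half-width (Th).
#' @return list `(runs, features, truth)`; `truth` has one row per feature:
#'   main/contaminant record ids, mixing weight, chimeric flag.
#' @export
simulate_dda_run <- function(library_path, manifest, n_features,
                             chimera_fraction = 0.5,
                             weights_range = c(0.1, 0.9), noise_cv = 0.05,
                             n_replicates = 1, seed = 1L, peak_sigma = 4,
                             scan_period = 1, isolation_halfwidth = 0.75) {
  set.seed(seed)
  lib <- open_library(library_path)
  on.exit(close_library(lib))
  n_chim <- round(n_features * chimera_fraction)
  pairs <- manifest[!is.na(manifest$partner_of), , drop = FALSE]
  if (nrow(pairs) < n_chim) {
    stop("chimera_fraction exceeds feasible pairings: need ", n_chim,
         " paired compounds, library has ", nrow(pairs))
  }
  singles <- manifest[is.na(manifest$partner_of) &
                        !manifest$record_id %in% pairs$partner_of, , drop = FALSE]
  if (nrow(singles) < n_features - n_chim) {
    stop("not enough unpaired compounds for clean features")
  }
  chim_rows <- pairs[sample.int(nrow(pairs), n_chim), , drop = FALSE]
  clean_rows <- singles[sample.int(nrow(singles), n_features - n_chim), , drop = FALSE]
  recs <- library_records(lib)
  names(recs) <- vapply(recs, function(r) as.character(r$record_id), "")
  spec_of <- function(rid) normalize_spectrum(recs[[as.character(rid)]]$spectrum)
  truth <- data.frame(
    feature_id = paste0("F", seq_len(n_features)),
    main_record = c(chim_rows$partner_of, clean_rows$record_id),
    contaminant_record = c(chim_rows$record_id, rep(NA_integer_, nrow(clean_rows))),
    weight = NA_real_, is_chimeric = c(rep(TRUE, n_chim),
                                       rep(FALSE, nrow(clean_rows))))
  truth$weight[truth$is_chimeric] <- stats::runif(n_chim, weights_range[1],
                                                  weights_range[2])
  truth$rt <- 60 + (seq_len(n_features) - 1) * 30
  truth$mz <- manifest$precursor_mz[match(truth$main_record, manifest$record_id)]
  truth$contaminant_mz <- manifest$precursor_mz[match(truth$contaminant_record,
                                                      manifest$record_id)]
  features <- ms1_features(mz_med = truth$mz, rt_med = truth$rt,
                           intensity = 1e6, feature_id = truth$feature_id)
  rt_grid <- seq(30, max(truth$rt) + 30, by = scan_period)
  runs <- lapply(seq_len(n_replicates), function(rep_k) {
    ms1 <- lapply(rt_grid, function(t) {
      mzv <- numeric(0); iv <- numeric(0)
      for (i in seq_len(n_features)) {
        g <- gaussian_peak(t, truth$rt[i], peak_sigma)
        if (g < 1e-4) next
        w <- if (truth$is_chimeric[i]) truth$weight[i] else 1
        f_main <- manifest$formula[manifest$record_id == truth$main_record[i]]
        iso <- theoretical_isotope_pattern(f_main)
        amp <- 1e6 * w * g
        mzv <- c(mzv, truth$mz[i], truth$mz[i] + NEUTRON_SHIFT,
                 truth$mz[i] + 2 * NEUTRON_SHIFT)
        iv <- c(iv, amp, amp * iso[["M1"]], amp * iso[["M2"]])
        if (truth$is_chimeric[i]) {
          mzv <- c(mzv, truth$contaminant_mz[i])
          iv <- c(iv, 1e6 * (1 - truth$weight[i]) * g)
        }
      }
      if (!length(mzv)) { mzv <- 400; iv <- 1 }  # keep scans non-empty
      spectrum(mzv, iv, precursor_rt = t, ms_level = 1L,
               source_id = sprintf("ms1_%d_%0.1f", rep_k, t))
    })
    ms2 <- lapply(seq_len(n_features), function(i) {
      main_sp <- spec_of(truth$main_record[i])
      if (truth$is_chimeric[i]) {
        con_sp <- spec_of(truth$contaminant_record[i])
        w <- truth$weight[i]
        al <- align_spectra(list(main_sp, con_sp), 0.005)
        mix <- w * al$intensity[, 1] + (1 - w) * al$intensity[, 2]
        mzv <- al$axis; iv <- mix
      } else {
        mzv <- main_sp$mz; iv <- main_sp$intensity
      }
      iv <- iv * lognormal_noise(length(iv), noise_cv)
      spectrum(mzv, iv, precursor_mz = truth$mz[i],
               precursor_rt = truth$rt[i] + 0.3, ms_level = 2L,
               source_id = paste0(truth$feature_id[i], "_rep", rep_k),
               isolation_lower = truth$mz[i] - isolation_halfwidth,
               isolation_upper = truth$mz[i] + isolation_halfwidth)
    })
    ms_run(ms1, ms2)
  })
  list(runs = runs, features = features, truth = truth)
}

#' Simulate a SWATH-DIA run with known co-elution structure
#'
#' Each acquisition cycle holds one full MS1 scan followed by one MS2 scan
#' per SWATH window. Compounds elute as Gaussian peaks; their fragments are
#' superposed into the MS2 scans of the window containing the precursor.
#' Ground truth records each compound's window, apex RT and fragment set.
#'
#' @param library_path path to a synthetic library.
#' @param manifest its manifest.
#' @param window_table data frame `(index, lower_mz, upper_mz)`; windows
#'   may overlap, precursors resolve to the nearest window center.
#' @param compounds data frame `(record_id, rt, amplitude)`; defaults to
#'   all in-window library compounds spaced 30 s apart at amplitude 1e6.
#' @param noise_cv multiplicative noise CV on fragment trace intensities.
#' @param seed integer seed.
#' @param peak_sigma chromatographic peak sigma (s).
#' @param cycle_period seconds per acquisition cycle.
#' @return list `(run, features, truth)`; `truth` has one row per compound
#'   (record_id, window, rt, fragment m/z list-column).
#' @export
simulate_swath_run <- function(library_path, manifest, window_table,
                               compounds = NULL, noise_cv = 0, seed = 1L,
                               peak_sigma = 4, cycle_period = 1.5) {
  set.seed(seed)
  lib <- open_library(library_path)
  on.exit(close_library(lib))
  win_of <- function(pmz) {
    hit <- window_table[window_table$lower_mz <= pmz &
                          pmz <= window_table$upper_mz, , drop = FALSE]
    if (!nrow(hit)) return(NA_integer_)
    centers <- (hit$lower_mz + hit$upper_mz) / 2
    hit$index[which.min(abs(centers - pmz))]
  }
  if (is.null(compounds)) {
    wi <- vapply(manifest$precursor_mz, win_of, 1L)
    ok <- which(!is.na(wi))
    compounds <- data.frame(record_id = manifest$record_id[ok],
                            rt = 60 + (seq_along(ok) - 1) * 30,
                            amplitude = 1e6)
  }
  wins <- vapply(manifest$precursor_mz[match(compounds$record_id,
                                             manifest$record_id)], win_of, 1L)
  if (any(is.na(wins))) {
    stop("precursor outside all SWATH windows for record(s) ",
         paste(compounds$record_id[is.na(wins)], collapse = ", "))
  }
  recs <- library_records(lib)
  names(recs) <- vapply(recs, function(r) as.character(r$record_id), "")
  specs <- lapply(compounds$record_id, function(rid)
    normalize_spectrum(recs[[as.character(rid)]]$spectrum))
  truth <- data.frame(record_id = compounds$record_id, window = wins,
                      rt = compounds$rt,
                      precursor_mz = manifest$precursor_mz[match(compounds$record_id,
                                                                 manifest$record_id)])
  truth$fragments <- I(lapply(specs, `[[`, "mz"))
  cycle_starts <- seq(30, max(compounds$rt) + 30, by = cycle_period)
  n_win <- nrow(window_table)
  ms1 <- list(); ms2 <- list()
  for (t0 in cycle_starts) {
    mzv <- numeric(0); iv <- numeric(0)
    for (i in seq_len(nrow(compounds))) {
      g <- gaussian_peak(t0, compounds$rt[i], peak_sigma)
      if (g < 1e-4) next
      mzv <- c(mzv, truth$precursor_mz[i])
      iv <- c(iv, compounds$amplitude[i] * g)
    }
    if (!length(mzv)) { mzv <- 400; iv <- 1 }
    ms1[[length(ms1) + 1L]] <- spectrum(mzv, iv, precursor_rt = t0,
                                        ms_level = 1L)
    for (w in seq_len(n_win)) {
      t_scan <- t0 + cycle_period * w / (n_win + 1)
      fmz <- numeric(0); fint <- numeric(0)
      for (i in which(wins == window_table$index[w])) {
        g <- gaussian_peak(t_scan, compounds$rt[i], peak_sigma)
        if (g < 1e-4) next
        s <- specs[[i]]
        fmz <- c(fmz, s$mz)
        fint <- c(fint, s$intensity * compounds$amplitude[i] * g / 100 *
                    lognormal_noise(length(s$mz), noise_cv))
      }
      if (!length(fmz)) next
      center <- (window_table$lower_mz[w] + window_table$upper_mz[w]) / 2
      ms2[[length(ms2) + 1L]] <- spectrum(
        fmz, fint, precursor_mz = center, precursor_rt = t_scan,
        ms_level = 2L,
        isolation_lower = window_table$lower_mz[w],
        isolation_upper = window_table$upper_mz[w],
        window_index = window_table$index[w])
    }
  }
  run <- ms_run(ms1, ms2)
  features <- ms1_features(mz_med = truth$precursor_mz, rt_med = truth$rt,
                           intensity = compounds$amplitude,
                           feature_id = paste0("D", truth$record_id))
  list(run = run, features = features, truth = truth)
}
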