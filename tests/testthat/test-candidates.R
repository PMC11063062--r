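test_that("orphan isotopologues link to their monoisotopic parents", {
  ms1 <- sp(c(200.0000, 201.00336, 150.5016775, 150.0), c(1e6, 1e5, 4e5, 8e5),
            rt = 100, ms_level = 1L)
  # M+1 at z=1: parent 1.003355 below
  hit <- detect_orphan_isotopologue(c(201.00336, 1e5), ms1, charge_max = 2)
  expect_equal(hit$parent_mz, 200.0)
  expect_equal(hit$n, 1)
  expect_equal(hit$z, 1)
  # M+1 at z=2: spacing 0.5017
  hit2 <- detect_orphan_isotopologue(c(150.5016775, 4e5), ms1, charge_max = 2)
  expect_equal(hit2$parent_mz, 150.0)
  expect_equal(hit2$z, 2)
  # no centroid 1.0034/z below: none
  expect_null(detect_orphan_isotopologue(c(300.0, 1e5), ms1))
  # parent must be at least as intense
  weak <- sp(c(200.0, 201.00336), c(1e4, 1e6), rt = 100, ms_level = 1L)
  expect_null(detect_orphan_isotopologue(c(201.00336, 1e6), weak))
})

test_that("simulated M/M+1 pairs at both charges all link correctly", {
  set.seed(5)
  parents <- sort(runif(6, 150, 600))
  zs <- rep(1:2, 3)
  child <- parents + 1.003355 / zs
  ms1 <- sp(c(parents, child), c(rep(1e6, 6), rep(2e5, 6)), rt = 50,
            ms_level = 1L)
  for (i in seq_along(child)) {
    hit <- detect_orphan_isotopologue(c(child[i], 2e5), ms1, charge_max = 2)
    expect_equal(hit$parent_mz, parents[i], tolerance = 1e-6)
    expect_equal(hit$n, 1)
  }
})

test_that("isotopologue spectrum prediction splits by carbon retention", {
  # single fragment carrying all carbons: everything shifts
  parent <- spectrum(c(120), c(100), precursor_mz = 180,
                     formulas = c("C6H6O2"))
  pred <- predict_isotopologue_spectrum(parent, "C6H12O6", n = 1, z = 1)
  expect_equal(pred$mz, 120 + 1.003355, tolerance = 1e-9)
  expect_equal(pred$intensity, 100)

  # glucose-like: fragments with 2 and 4 of 6 carbons shift 1/3 and 2/3
  parent2 <- spectrum(c(60, 120), c(100, 100), precursor_mz = 180,
                      formulas = c("C2H4O2", "C4H8O4"))
  pred2 <- predict_isotopologue_spectrum(parent2, "C6H12O6", n = 1, z = 1)
  i_unshift_1 <- pred2$intensity[which.min(abs(pred2$mz - 60))]
  i_shift_1 <- pred2$intensity[which.min(abs(pred2$mz - 61.003355))]
  expect_equal(i_shift_1 / (i_shift_1 + i_unshift_1), 1 / 3, tolerance = 1e-9)
  i_unshift_2 <- pred2$intensity[which.min(abs(pred2$mz - 120))]
  i_shift_2 <- pred2$intensity[which.min(abs(pred2$mz - 121.003355))]
  expect_equal(i_shift_2 / (i_shift_2 + i_unshift_2), 2 / 3, tolerance = 1e-9)

  # m/z-ratio fallback when formulas are absent
  parent3 <- spectrum(c(90), c(100), precursor_mz = 180)
  pred3 <- predict_isotopologue_spectrum(parent3, n = 1, z = 1)
  expect_equal(pred3$intensity[1] / pred3$intensity[2], 1, tolerance = 1e-9)
  expect_error(predict_isotopologue_spectrum(parent, n = 3), "must be 1 or 2")
})

test_that("in-data clean spectra are found with nearer-wins selection", {
  clean_a <- sp(c(70, 90), c(100, 40), pmz = 250.1, rt = 104, ms_level = 2L,
                isolation_lower = 249.35, isolation_upper = 250.85)
  clean_b <- sp(c(75, 95), c(100, 40), pmz = 250.1, rt = 109, ms_level = 2L,
                isolation_lower = 249.35, isolation_upper = 250.85)
  ms1 <- list(sp(c(250.1), c(1e6), rt = 104, ms_level = 1L))
  run <- ms_run(ms1, list(clean_a, clean_b))
  hit <- find_in_data_clean_spectrum(250.1, run, rt = 100, ppm_tol = 10)
  expect_equal(hit$mz, clean_a$mz)  # 4 s beats 9 s
  expect_null(find_in_data_clean_spectrum(999.9, run, rt = 100))
  # both nearby scans chimeric: none
  ms1_chim <- list(sp(c(250.1, 250.4), c(1e6, 5e5), rt = 104, ms_level = 1L))
  run2 <- ms_run(ms1_chim, list(clean_a, clean_b))
  expect_null(find_in_data_clean_spectrum(250.1, run2, rt = 100))
})

test_that("library candidates maximize similarity to Spectrum 0", {
  path <- tiny_library(list(
    list(precursor_mz = 250.1, mz = c(80, 120, 160), intensity = c(100, 60, 30)),
    list(precursor_mz = 250.1, mz = c(55, 65, 75), intensity = c(100, 50, 25))))
  lib <- open_library(path)
  s0 <- sp(c(80, 120, 160, 200), c(100, 60, 30, 80), pmz = 250.1)
  pick <- select_library_candidate(250.1, lib, s0, ppm_tol = 10)
  expect_equal(pick$record$record_id, 1L)  # shares 3 fragments, not 0
  expect_gt(pick$similarity,
            spectral_similarity(library_records(lib)[[2]]$spectrum, s0))
  expect_null(select_library_candidate(999, lib, s0, 10))
  close_library(lib)
})

test_that("neighbor spectra are cleaned by elemental containment", {
  s <- spectrum(c(45.1, 28.05, 26.0), c(100, 50, 25),
                formulas = c("C3H9", "C2H4", "CH3Cl"), polarity = "positive")
  out <- clean_neighbor_spectrum(s, "C2H7NO3S")
  expect_equal(out$formulas, "C2H4")
  expect_length(out$mz, 1)
  # idempotent and never grows
  again <- clean_neighbor_spectrum(out, "C2H7NO3S")
  expect_equal(again$mz, out$mz)
  expect_lte(length(out$mz), length(s$mz))
})

test_that("class IV prediction walks the network and penalizes by similarity", {
  # unknown ion: [M+H]+ of C9H17NO8; its methylation neighbor C10H19NO8 is
  # in the library with fragments elementally compatible with the unknown
  unknown_mz <- adduct_mz("C9H17NO8", "[M+H]+")
  s0 <- sp(c(100, 200), c(100, 50), pmz = 350)
  path <- tiny_library(list(
    list(precursor_mz = adduct_mz("C10H19NO8", "[M+H]+"),
         formula = "C10H19NO8",
         mz = c(100, 200), intensity = c(100, 50),
         fragment_formulas = c("C4H6O3", "C8H10NO5"))))
  lib <- open_library(path)
  cand <- predict_unknown_spectrum(unknown_mz, lib, s0, ppm_tol = 10)
  expect_false(is.null(cand))
  expect_equal(cand$provenance, "IV")
  # cleaned neighbor spectrum equals s0 exactly: similarity 1, no penalty
  expect_equal(cand$similarity_to_spectrum0, 1, tolerance = 1e-9)
  expect_equal(cand$penalty, 0, tolerance = 1e-9)
  close_library(lib)

  # penalty endpoints and linearity from the constructor contract
  totally_off <- sp(c(500, 600), c(100, 50), pmz = 350)
  path2 <- tiny_library(list(
    list(precursor_mz = adduct_mz("C10H19NO8", "[M+H]+"),
         formula = "C10H19NO8",
         mz = c(100, 200), intensity = c(100, 50),
         fragment_formulas = c("C4H6O3", "C8H10NO5"))))
  lib2 <- open_library(path2)
  cand2 <- predict_unknown_spectrum(unknown_mz, lib2, totally_off, ppm_tol = 10)
  expect_false(is.null(cand2))
  expect_equal(cand2$similarity_to_spectrum0, 0, tolerance = 1e-9)
  expect_equal(cand2$penalty, 10, tolerance = 1e-9)
  close_library(lib2)
})

test_that("candidate assembly resolves classes in order and drops orphans ions", {
  lib <- make_synthetic_library(30, seed = 11, paired_fraction = 0.6)
  sim <- simulate_dda_run(lib$path, lib$manifest, n_features = 4,
                          chimera_fraction = 0.5, seed = 3)
  run <- sim$runs[[1]]
  L <- open_library(lib$path)
  i <- which(sim$truth$is_chimeric)[1]
  asg <- assign_ms2_to_features(run, sim$features, 10, 15)[[i]]
  s0 <- merge_coassigned_spectra(asg)
  a <- assess_chimeric(sim$features[i, ], s0, run)
  cands <- assemble_candidates(a, run, L)
  prov <- vapply(cands, `[[`, "", "provenance")
  expect_equal(prov[1], "MAIN")
  expect_true(all(prov[-1] %in% c("I", "II", "III", "IV")))
  expect_equal(length(cands), 1 + nrow(a$contamination_ions))
  # the contaminant here has a library record: resolved as class III
  expect_true("III" %in% prov)
  close_library(L)
})
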