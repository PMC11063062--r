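test_that("library generation is valid, constrained, and seed-deterministic", {
  a <- make_synthetic_library(50, seed = 1, path = tempfile(fileext = ".sqlite"))
  expect_equal(nrow(a$manifest), 50)
  L <- open_library(a$path)
  recs <- library_records(L)
  expect_length(recs, 50)
  for (r in recs) {
    expect_true(all(r$spectrum$mz < r$precursor_mz))
    expect_equal(max(r$spectrum$intensity), 100)
    # precursor consistent with the formula under [M+H]+
    expect_equal(r$precursor_mz, adduct_mz(r$formula, "[M+H]+"),
                 tolerance = 1e-6)
  }
  close_library(L)
  b <- make_synthetic_library(50, seed = 1, path = tempfile(fileext = ".sqlite"))
  expect_identical(readBin(a$path, "raw", file.size(a$path)),
                   readBin(b$path, "raw", file.size(b$path)))
  c2 <- make_synthetic_library(50, seed = 2, path = tempfile(fileext = ".sqlite"))
  expect_false(identical(a$manifest$formula, c2$manifest$formula))
})

test_that("DDA simulation honors the chimera fraction and isotope physics", {
  lib <- make_synthetic_library(40, seed = 11, paired_fraction = 0.8)
  sim <- simulate_dda_run(lib$path, lib$manifest, n_features = 10,
                          chimera_fraction = 0.5, seed = 3)
  expect_equal(sum(sim$truth$is_chimeric), 5)
  expect_true(all(sim$truth$weight[sim$truth$is_chimeric] >= 0.1 &
                    sim$truth$weight[sim$truth$is_chimeric] <= 0.9))
  # chimera_fraction 0 gives only clean assessments
  sim0 <- simulate_dda_run(lib$path, lib$manifest, n_features = 5,
                           chimera_fraction = 0, seed = 3)
  run0 <- sim0$runs[[1]]
  for (i in seq_len(5)) {
    asg <- assign_ms2_to_features(run0, sim0$features[i, ], 10, 15)[[1]]
    a <- assess_chimeric(sim0$features[i, ], merge_coassigned_spectra(asg), run0)
    expect_false(a$is_chimeric)
  }
  # isotope satellites in the MS1 scans match theory
  i <- 1
  f_main <- lib$manifest$formula[lib$manifest$record_id == sim0$truth$main_record[i]]
  theo <- theoretical_isotope_pattern(f_main)
  rts <- vapply(run0$ms1, `[[`, 1.0, "precursor_rt")
  scan <- run0$ms1[[which.min(abs(rts - sim0$truth$rt[i]))]]
  mono <- which.min(abs(scan$mz - sim0$truth$mz[i]))
  m1 <- which.min(abs(scan$mz - (sim0$truth$mz[i] + 1.003355)))
  expect_equal(scan$intensity[m1] / scan$intensity[mono], theo[["M1"]],
               tolerance = 1e-6)
  # infeasible chimera demand errors
  expect_error(simulate_dda_run(lib$path, lib$manifest, n_features = 40,
                                chimera_fraction = 1, seed = 1),
               "feasible pairings")
})

test_that("replicate runs share truth but differ in noise", {
  lib <- make_synthetic_library(30, seed = 11, paired_fraction = 0.6)
  sim <- simulate_dda_run(lib$path, lib$manifest, n_features = 4,
                          chimera_fraction = 0.5, noise_cv = 0.1,
                          n_replicates = 3, seed = 9)
  expect_length(sim$runs, 3)
  s1 <- sim$runs[[1]]$ms2[[1]]$intensity
  s2 <- sim$runs[[2]]$ms2[[1]]$intensity
  expect_false(identical(s1, s2))
  expect_equal(sim$runs[[1]]$ms2[[1]]$mz, sim$runs[[2]]$ms2[[1]]$mz)
})

test_that("generated runs survive mzML serialization", {
  lib <- make_synthetic_library(30, seed = 11, paired_fraction = 0.6)
  sim <- simulate_dda_run(lib$path, lib$manifest, n_features = 3,
                          chimera_fraction = 0, seed = 2)
  f <- tempfile(fileext = ".mzML")
  write_ms_run(sim$runs[[1]], f)
  back <- read_ms_run(f)
  expect_length(back$ms1, length(sim$runs[[1]]$ms1))
  expect_length(back$ms2, length(sim$runs[[1]]$ms2))
  k <- length(back$ms2)
  expect_equal(back$ms2[[k]]$mz, sim$runs[[1]]$ms2[[k]]$mz, tolerance = 1e-6)

  wins <- data.frame(index = 1:10, lower_mz = seq(95, 545, by = 50),
                     upper_mz = seq(146, 596, by = 50))
  dsim <- simulate_swath_run(lib$path, lib$manifest, wins, seed = 7)
  f2 <- tempfile(fileext = ".mzML")
  write_ms_run(dsim$run, f2)
  back2 <- read_ms_run(f2)
  expect_length(back2$ms2, length(dsim$run$ms2))
  # window indices are regenerated on read: identical isolation bounds get
  # identical indices, ordered by lower bound, for every occupied window
  orig_lo <- vapply(dsim$run$ms2, `[[`, 1.0, "isolation_lower")
  back_lo <- vapply(back2$ms2, `[[`, 1.0, "isolation_lower")
  back_wi <- vapply(back2$ms2, `[[`, 1L, "window_index")
  expect_equal(sort(unique(back_wi)), seq_along(unique(orig_lo)))
  expect_equal(back_wi, as.integer(factor(rank(back_lo, ties.method = "min"))))
})

test_that("SWATH truth records window membership and cluster separation", {
  lib <- make_synthetic_library(12, seed = 5)
  wins <- data.frame(index = 1:10, lower_mz = seq(95, 545, by = 50),
                     upper_mz = seq(146, 596, by = 50))
  sim <- simulate_swath_run(lib$path, lib$manifest, wins, seed = 7)
  for (i in seq_len(nrow(sim$truth))) {
    w <- wins[wins$index == sim$truth$window[i], ]
    expect_true(w$lower_mz <= sim$truth$precursor_mz[i] &&
                  sim$truth$precursor_mz[i] <= w$upper_mz)
  }
  # forced co-elution in one window: truth has two apex groups 20 s apart
  two <- sim$truth$record_id[1:2]
  comp <- data.frame(record_id = two, rt = c(100, 120), amplitude = 1e6)
  sim2 <- simulate_swath_run(lib$path, lib$manifest, wins, compounds = comp,
                             seed = 8)
  expect_equal(sim2$truth$rt, c(100, 120))
  # out-of-window precursor errors
  tiny_wins <- data.frame(index = 1, lower_mz = 100, upper_mz = 101)
  expect_error(simulate_swath_run(lib$path, lib$manifest, tiny_wins,
                                  compounds = comp, seed = 1),
               "outside all SWATH windows")
})
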