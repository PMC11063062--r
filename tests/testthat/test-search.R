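test_that("dot-product similarity matches hand-computed cosines", {
  a <- sp(c(100, 200), c(1, 1))
  b <- sp(c(100), c(1))
  expect_equal(dot_product_similarity(a, b), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(dot_product_similarity(a, a), 1)
  expect_equal(dot_product_similarity(a, sp(c(500, 600), c(1, 1))), 0)
  expect_equal(dot_product_similarity(a, b), dot_product_similarity(b, a))
  expect_warning(
    expect_equal(dot_product_similarity(a, sp(numeric(0), numeric(0))), 0),
    "empty")
})

test_that("entropy similarity matches the hand-evaluated formula", {
  a <- sp(c(100), c(1.0))
  b <- sp(c(100, 200), c(0.5, 0.5))
  # S_a=0, S_b=ln2, S_merged=-(0.75 ln 0.75 + 0.25 ln 0.25)
  sm <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expected <- 1 - (2 * sm - 0 - log(2)) / log(4)
  expect_equal(entropy_similarity(a, b), expected, tolerance = 1e-12)
  expect_equal(expected, 0.6887, tolerance = 1e-4)
  expect_equal(entropy_similarity(a, a), 1)
  # two disjoint single fragments: exactly 0
  expect_equal(entropy_similarity(a, sp(c(300), c(1))), 0, tolerance = 1e-12)
  expect_equal(entropy_similarity(a, b), entropy_similarity(b, a))
})

test_that("the exponential deviation kernel has the stated shape", {
  expect_equal(deviation_similarity(0, 5), 1)
  expect_equal(deviation_similarity(5, 5), exp(-1))
  expect_lt(deviation_similarity(50, 5), 1e-4)
  expect_equal(deviation_similarity(-3, 5), deviation_similarity(3, 5))
  expect_error(deviation_similarity(1, 0), "positive")
})

test_that("the composite score follows the 3.5/2.5 denominators", {
  expect_equal(matching_score(1, 1, 1, 1), 100)
  expect_equal(matching_score(1, 1, NULL, 1), 100)
  expect_equal(matching_score(0, 0, 0, 0), 0)
  expect_equal(matching_score(0.8, 0.9, 0.7, 0.5),
               (0.8 + 0.9 + 0.7 + 0.25) / 3.5 * 100, tolerance = 1e-12)
  expect_error(matching_score(1.2, 0.5, NULL, 0), "in \\[0, 1\\]")
  # monotone non-decreasing in each component
  base <- matching_score(0.5, 0.5, 0.5, 0.5)
  expect_gte(matching_score(0.6, 0.5, 0.5, 0.5), base)
  expect_gte(matching_score(0.5, 0.6, 0.5, 0.5), base)
  expect_gte(matching_score(0.5, 0.5, 0.6, 0.5), base)
  expect_gte(matching_score(0.5, 0.5, 0.5, 0.6), base)
})

test_that("a record self-match scores 100 and ranking is order-invariant", {
  lib_info <- make_synthetic_library(25, seed = 77)
  L <- open_library(lib_info$path)
  recs <- library_records(L)
  r <- recs[[3]]
  q <- r$spectrum
  q$precursor_rt <- 300
  res <- search_library(q, L, search_options(ppm_tol = 10),
                        observed_isotope = theoretical_isotope_pattern(r$formula),
                        query_id = "self")
  expect_equal(res$record_id[1], r$record_id)
  expect_equal(res$matching_score[1], 100, tolerance = 1e-9)
  # no precursor match: empty table
  none <- search_library(sp(c(100), c(1), pmz = 9999), L)
  expect_equal(nrow(none), 0)
  close_library(L)
})

test_that("shared fragments rank the right record first among isobars", {
  path <- tiny_library(list(
    list(precursor_mz = 250.1, mz = c(80, 120, 160), intensity = c(100, 60, 30),
         inchikey = "AAAAAAAAAAAAAA-AAAAAAAA-A"),
    list(precursor_mz = 250.1, mz = c(55, 65, 75), intensity = c(100, 50, 25),
         inchikey = "BBBBBBBBBBBBBB-BBBBBBBB-B")))
  L <- open_library(path)
  q <- sp(c(80, 120, 160), c(90, 65, 25), pmz = 250.1)
  res <- search_library(q, L)
  expect_equal(res$record_id, c(1L, 2L))
  expect_gt(res$matching_score[1], res$matching_score[2])
  close_library(L)
})

test_that("neutral-loss spectra mirror fragments against the precursor", {
  s <- sp(c(100, 250), c(80, 100), pmz = 300)
  nl <- neutral_loss_spectrum(s)
  expect_equal(nl$mz, c(50, 200))
  expect_equal(nl$intensity, c(100, 80))
  # involution: applying twice restores the original m/z set
  back <- neutral_loss_spectrum(nl)
  expect_equal(sort(back$mz), sort(s$mz))
  # a fragment at the precursor is dropped
  s2 <- sp(c(100, 300), c(50, 10), pmz = 300)
  expect_equal(neutral_loss_spectrum(s2)$mz, 200)
  expect_error(neutral_loss_spectrum(sp(c(100), c(1))), "precursor")
})

test_that("neutral-loss fallback finds transformation-shifted analogues", {
  # compound X in the library; query is X's fragment pattern with the
  # precursor shifted by +CH2 so NL patterns coincide
  x_formula <- "C9H17NO8"
  x_pmz <- adduct_mz(x_formula, "[M+H]+")
  x_mz <- c(x_pmz - 150, x_pmz - 60)
  path <- tiny_library(list(
    list(precursor_mz = x_pmz, formula = x_formula, mz = x_mz,
         intensity = c(100, 40))))
  L <- open_library(path)
  nl_path <- tempfile(fileext = ".sqlite")
  derive_neutral_loss_library(L, nl_path)
  NL <- open_library(nl_path)
  q_pmz <- adduct_mz("C10H19NO8", "[M+H]+")  # +CH2 relative to X
  q <- sp(c(q_pmz - 150, q_pmz - 60), c(100, 40), pmz = q_pmz,
          polarity = "positive")
  res <- neutral_loss_search(q, NL, search_options(), best_standard_score = 0)
  expect_gt(nrow(res), 0)
  expect_equal(res$formula[1], x_formula)
  expect_equal(res$match_kind[1], "neutral_loss")
  expect_equal(res$ms2_sim[1], 1, tolerance = 1e-6)
  # threshold contract: a good standard match skips the fallback
  skipped <- neutral_loss_search(q, NL, search_options(),
                                 best_standard_score = 85)
  expect_equal(nrow(skipped), 0)
  close_library(L); close_library(NL)
})

test_that("export collapses duplicate InChIKeys and truncates to top N", {
  m <- data.frame(
    query_id = "F1",
    record_id = 1:5,
    compound_name = paste0("c", 1:5),
    formula = "C6H12O6",
    inchikey = c("KEY1-X-N", "KEY1-X-N", "KEY2-X-N", "KEY3-X-N", "KEY4-X-N"),
    adduct = "[M+H]+",
    matching_score = c(90, 70, 80, 60, 50),
    ms2_sim = 0.9, ms1_sim = 1, rt_sim = NA_real_, isotope_sim = 0.5,
    match_kind = "standard", stringsAsFactors = FALSE)
  out <- export_results(m, top_n = 3)
  expect_equal(nrow(out), 3)
  expect_equal(out$matching_score, c(90, 80, 60))  # KEY1 keeps only 90
  expect_false(any(duplicated(out$inchikey)))
  # writes a header-only file for empty input
  f <- tempfile(fileext = ".csv")
  export_results(m[0, ], top_n = 3, path = f)
  expect_equal(nrow(utils::read.csv(f)), 0)
})
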