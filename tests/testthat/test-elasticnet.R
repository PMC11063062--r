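make_problem <- function(y_sp, cand_specs, mz_tol = 0.01, penalties = NULL) {
  cands <- lapply(seq_along(cand_specs), function(i) {
    prov <- if (i == 1) "MAIN" else "III"
    structure(list(ion_mz = cand_specs[[i]]$precursor_mz,
                   spectrum = cand_specs[[i]], provenance = prov,
                   similarity_to_spectrum0 = NA_real_,
                   penalty = if (is.null(penalties)) 0 else penalties[i]),
              class = "ms2_candidate")
  })
  build_design_matrix(y_sp, cands, mz_tol)
}

test_that("design matrix aligns spectra on a merged union axis", {
  s0 <- sp(c(100, 200, 300), c(100, 50, 25), pmz = 400)
  same <- sp(c(100, 200, 300), c(100, 50, 25), pmz = 400)
  prob <- make_problem(s0, list(same))
  # single identical candidate: column proportional to y
  expect_equal(ncol(prob$X), 1)
  expect_equal(prob$X[, 1], prob$y / sqrt(sum(prob$y^2)), tolerance = 1e-12)
  expect_equal(sum(prob$X[, 1]^2), 1)  # unit norm

  # disjoint candidates give orthogonal columns
  a <- sp(c(100, 200), c(100, 50), pmz = 400)
  b <- sp(c(500, 600), c(100, 20), pmz = 400)
  prob2 <- make_problem(s0, list(a, b))
  expect_equal(sum(prob2$X[, 1] * prob2$X[, 2]), 0)

  # axis length equals a brute-force union merge
  set.seed(8)
  specs <- lapply(1:3, function(i) sp(sort(runif(5, 50, 500)), runif(5, 1, 100),
                                      pmz = 600))
  prob3 <- make_problem(specs[[1]], specs[2:3], mz_tol = 0.5)
  all_mz <- sort(unlist(lapply(specs, `[[`, "mz")))
  n_groups <- sum(diff(all_mz) > 0.5) + 1
  expect_length(prob3$axis, n_groups)
  expect_error(build_design_matrix(sp(numeric(0), numeric(0)), list()), "empty|candidate")
})

test_that("the unpenalized solver matches the NNLS active-set oracle", {
  set.seed(13)
  for (k in 1:10) {
    n <- 25; p <- 4
    X <- matrix(abs(rnorm(n * p)), n, p)
    X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
    beta_true <- c(2, 0, 1.5, 0)
    y <- as.numeric(X %*% beta_true) + abs(rnorm(n, 0, 0.01))
    prob <- structure(list(y = y, X = X, axis = seq_len(n),
                           penalty_factors = rep(1, p),
                           col_scale = rep(1, p),
                           provenance = c("MAIN", rep("III", p - 1)),
                           ion_mz = rep(NA_real_, p), main_col = 1L),
                      class = "ms2_deconv_problem")
    sol <- solve_elastic_net(prob, alpha = 0, lambda = 0)
    expect_lt(max(abs(sol$beta - oracle_nnls(X, y))), 1e-4)
  }
})

test_that("the penalized solver matches a projected quasi-Newton oracle", {
  # with beta >= 0 the objective is a smooth quadratic on the orthant, so
  # box-constrained BFGS is an exact independent oracle at any alpha
  set.seed(21)
  for (alpha in c(0, 0.5, 1)) {
    n <- 30; p <- 3
    X <- matrix(abs(rnorm(n * p)), n, p)
    X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
    y <- as.numeric(X %*% c(1.5, 0.8, 0)) + abs(rnorm(n, 0, 0.05))
    pf <- c(1, 1, 5)
    lambda <- 0.3
    prob <- structure(list(y = y, X = X, axis = seq_len(n),
                           penalty_factors = pf, col_scale = rep(1, p),
                           provenance = c("MAIN", "III", "IV"),
                           ion_mz = rep(NA_real_, p), main_col = 1L),
                      class = "ms2_deconv_problem")
    sol <- solve_elastic_net(prob, alpha, lambda)
    obj <- function(b) sum((y - X %*% b)^2) +
      lambda * sum(pf * ((1 - alpha) / 2 * b^2 + alpha * b))
    orc <- optim(rep(0.5, p), obj, method = "L-BFGS-B", lower = 0,
                 control = list(factr = 1e3))
    expect_lt(max(abs(sol$beta - orc$par)), 1e-4)
    expect_lte(obj(sol$beta), orc$value + 1e-8)
  }
})

test_that("solver limits behave: zero response, heavy shrinkage", {
  X <- diag(3)
  prob <- structure(list(y = rep(0, 3), X = X, axis = 1:3,
                         penalty_factors = rep(1, 3), col_scale = rep(1, 3),
                         provenance = c("MAIN", "III", "III"),
                         ion_mz = rep(NA_real_, 3), main_col = 1L),
                    class = "ms2_deconv_problem")
  expect_equal(solve_elastic_net(prob, 0.5, 1)$beta, rep(0, 3))
  prob$y <- c(1, 2, 3)
  big <- solve_elastic_net(prob, 1, 1e9)
  expect_equal(big$beta, rep(0, 3))
  expect_true(big$failed)
})

test_that("grid optimization evaluates 110 combinations and minimizes residue", {
  set.seed(3)
  s0 <- sp(sort(runif(20, 50, 500)), runif(20, 10, 100), pmz = 600)
  c1 <- sp(s0$mz[1:12], s0$intensity[1:12], pmz = 600)
  c2 <- sp(s0$mz[9:20], s0$intensity[9:20], pmz = 600)
  prob <- make_problem(s0, list(c1, c2))
  best <- grid_optimize(prob)
  grid <- attr(best, "grid")
  expect_equal(attr(best, "n_evaluated"), 110)
  expect_equal(nrow(grid), 110)
  expect_length(unique(grid$alpha), 11)
  expect_length(unique(round(grid$lambda, 10)), 10)
  expect_true(all(best$residue <= grid$residue + 1e-12))
  expect_true(all(grid$residue >= 0))
})

test_that("grid-tuned fit recovers known mixing proportions", {
  set.seed(17)
  a <- normalize_spectrum(sp(sort(runif(8, 50, 400)), runif(8, 10, 100), pmz = 500))
  b <- normalize_spectrum(sp(sort(runif(8, 50, 400)), runif(8, 10, 100), pmz = 500))
  al <- align_spectra(list(a, b), 0.01)
  y <- sp(al$axis, 0.7 * al$intensity[, 1] + 0.3 * al$intensity[, 2], pmz = 500)
  prob <- make_problem(y, list(a, b))
  best <- grid_optimize(prob)
  w <- best$beta / prob$col_scale
  ratio <- w[1] / w[2]
  expect_lt(abs(ratio - 7 / 3) / (7 / 3), 0.05)
  # exact-fit case: all weight on the matching candidate
  prob1 <- make_problem(a, list(a, b))
  best1 <- grid_optimize(prob1)
  expect_lt(best1$residue, 1e-3 * sum(prob1$y^2))
  expect_gt(best1$beta[1], 0)
})

test_that("contaminant subtraction recovers the clean spectrum or fails safely", {
  set.seed(29)
  a <- normalize_spectrum(sp(sort(runif(8, 50, 400)), runif(8, 10, 100), pmz = 500))
  b <- normalize_spectrum(sp(sort(runif(8, 60, 410)), runif(8, 10, 100), pmz = 510))
  al <- align_spectra(list(a, b), 0.01)
  chim <- sp(al$axis, 0.6 * al$intensity[, 1] + 0.4 * al$intensity[, 2], pmz = 500)
  prob <- make_problem(chim, list(a, b))
  sol <- grid_optimize(prob)
  out <- subtract_contaminants(chim, prob, sol)
  expect_false(out$failed)
  # deconvolved closer to truth than the raw chimera (both dot product)
  expect_gt(dot_product_similarity(out$spectrum, a),
            dot_product_similarity(normalize_spectrum(chim), a))

  # beta_MAIN = 0 returns spectrum0 unchanged with failed = TRUE
  forced <- sol
  forced$beta[1] <- 0
  out2 <- subtract_contaminants(chim, prob, forced)
  expect_true(out2$failed)
  expect_equal(out2$spectrum$mz, normalize_spectrum(chim)$mz)

  # all contaminant betas zero: output is just normalized spectrum0
  loner <- make_problem(chim, list(a))
  sol_l <- solve_elastic_net(loner, 0, 0)
  out3 <- subtract_contaminants(chim, loner, sol_l)
  expect_false(out3$failed)
  expect_equal(out3$spectrum$intensity, normalize_spectrum(chim)$intensity)
})

test_that("identical inputs give bit-identical solutions", {
  set.seed(37)
  s0 <- sp(sort(runif(10, 50, 400)), runif(10, 10, 100), pmz = 500)
  c1 <- sp(s0$mz[1:6], s0$intensity[1:6] * 0.9, pmz = 500)
  c2 <- sp(s0$mz[5:10], s0$intensity[5:10] * 1.1, pmz = 510)
  p1 <- make_problem(s0, list(c1, c2))
  p2 <- make_problem(s0, list(c1, c2))
  r1 <- grid_optimize(p1); r2 <- grid_optimize(p2)
  expect_identical(r1$beta, r2$beta)
  expect_identical(r1$alpha, r2$alpha)
  expect_identical(r1$lambda, r2$lambda)
})

test_that("end-to-end DDA deconvolution handles clean, covered, and uncovered cases", {
  lib <- make_synthetic_library(30, seed = 11, paired_fraction = 0.6)
  sim <- simulate_dda_run(lib$path, lib$manifest, n_features = 4,
                          chimera_fraction = 0.5, noise_cv = 0.05, seed = 3)
  run <- sim$runs[[1]]
  L <- open_library(lib$path)
  for (i in seq_len(nrow(sim$features))) {
    res <- deconvolve_dda(sim$features[i, ], run, L)
    expect_equal(res$is_chimeric, sim$truth$is_chimeric[i])
    if (sim$truth$is_chimeric[i]) {
      expect_false(res$failed)
      expect_gt(res$solution$beta[1], 0)
      expect_true(all(res$solution$beta >= 0))
      expect_true(all(res$spectrum$intensity >= 0))
    } else {
      expect_null(res$solution)  # clean features bypass the regression
    }
  }
  # chimeric feature with no library and no candidates: falls back, flagged
  res_nolib <- suppressWarnings(
    deconvolve_dda(sim$features[which(sim$truth$is_chimeric)[1], ], run,
                   library = NULL))
  expect_true(res_nolib$failed)
  close_library(L)
})
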