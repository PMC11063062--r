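# Penalized elastic-net deconvolution of chimeric spectra.
#
# The chimeric Spectrum 0 is modelled as a non-negative mixture of candidate
# component spectra on a shared m/z axis:
#
#   minimize  sum((y - X beta)^2) + lambda * sum_j pf_j * P_alpha(beta_j)
#   where     P_alpha(b) = (1 - alpha)/2 * b^2 + alpha * |b|,   beta >= 0
#
# pf_j is a per-column penalty factor: 1 for candidates of classes I-III and
# the main ion, (1 + penalty) for transformation-network predictions (class
# IV, penalty in [0, 10]). The (alpha, lambda) pair is auto-tuned over a
# fixed 11 x 10 grid and the minimal-RSS solution wins. Because beta >= 0
# the L1 term is linear and the objective is a smooth convex quadratic on
# the non-negative orthant; it is solved by cyclic coordinate descent with
# exact per-coordinate minimizers.

#' Build the aligned regression problem from Spectrum 0 and candidates
#'
#' The m/z axis is the union of all fragment m/z values merged at `mz_tol`;
#' the response `y` holds Spectrum 0 intensities on that axis and the design
#' matrix one column per candidate (MAIN first). Columns are scaled to unit
#' Euclidean norm; the scale factors are retained so coefficients can be
#' mapped back to intensity units.
#'
#' @param spectrum0 the chimeric `ms2_spectrum` (non-empty).
#' @param candidates list of `ms2_candidate` including one of provenance
#'   `"MAIN"`.
#' @param mz_tol axis merge tolerance (Th).
#' @return an object of class `ms2_deconv_problem` with fields `y`, `X`,
#'   `axis`, `penalty_factors`, `col_scale`, `provenance`, `ion_mz`,
#'   `main_col`.
#' @export
build_design_matrix <- function(spectrum0, candidates, mz_tol = 0.01) {
  if (!length(spectrum0$mz)) stop("empty Spectrum 0")
  if (!length(candidates)) stop("at least one candidate required")
  prov <- vapply(candidates, `[[`, "", "provenance")
  if (!any(prov == "MAIN")) stop("MAIN candidate missing")
  ord <- order(prov != "MAIN")  # MAIN first, stable otherwise
  candidates <- candidates[ord]
  prov <- prov[ord]
  al <- align_spectra(c(list(spectrum0), lapply(candidates, `[[`, "spectrum")),
                      mz_tol)
  y <- al$intensity[, 1]
  X <- al$intensity[, -1, drop = FALSE]
  col_scale <- sqrt(colSums(X^2))
  col_scale[col_scale == 0] <- 1
  X <- sweep(X, 2, col_scale, "/")
  structure(list(
    y = y, X = X, axis = al$axis,
    penalty_factors = 1 + vapply(candidates, `[[`, 1.0, "penalty"),
    col_scale = col_scale,
    provenance = prov,
    ion_mz = vapply(candidates, `[[`, 1.0, "ion_mz"),
    main_col = 1L
  ), class = "ms2_deconv_problem")
}

#' Solve the non-negative penalized elastic net at fixed (alpha, lambda)
#'
#' Cyclic coordinate descent with exact coordinate updates: for column j,
#' `beta_j = max(0, x_j'(y - X_{-j} beta) - lambda*pf_j*alpha/2) /
#' (x_j'x_j + lambda*pf_j*(1-alpha)/2)` (the 1/2 appearing because the
#' objective's squared-error term is unscaled). Converges when the largest
#' coefficient change is below `tol` or after `max_sweeps` sweeps.
#'
#' @param problem an `ms2_deconv_problem`.
#' @param alpha elastic-net mixing in `[0, 1]` (1 = lasso, 0 = ridge).
#' @param lambda penalty strength, >= 0.
#' @param tol convergence threshold on the max coefficient change.
#' @param max_sweeps sweep cap; hitting it flags non-convergence.
#' @return an object of class `ms2_deconvolution`: coefficients `beta` (on
#'   the normalized columns), `beta_scaled` (intensity units), `alpha`,
#'   `lambda`, `residue` (unpenalized RSS), `objective` (penalized), and
#'   flags `converged`, `failed`.
#' @export
solve_elastic_net <- function(problem, alpha, lambda, tol = 1e-6,
                              max_sweeps = 1e4) {
  stopifnot(alpha >= 0, alpha <= 1, lambda >= 0)
  X <- problem$X; y <- problem$y
  pf <- problem$penalty_factors
  p <- ncol(X)
  xtx <- colSums(X^2)
  beta <- numeric(p)
  r <- y  # residual y - X beta
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    delta_max <- 0
    for (j in seq_len(p)) {
      bj <- beta[j]
      rho <- sum(X[, j] * r) + xtx[j] * bj
      num <- rho - lambda * pf[j] * alpha / 2
      den <- xtx[j] + lambda * pf[j] * (1 - alpha) / 2
      bnew <- if (den > 0) max(0, num / den) else 0
      if (bnew != bj) {
        r <- r - X[, j] * (bnew - bj)
        delta_max <- max(delta_max, abs(bnew - bj))
        beta[j] <- bnew
      }
    }
    if (delta_max < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("coordinate descent did not converge (alpha=%.1f, lambda=%.3g)",
                    alpha, lambda), call. = FALSE)
  }
  rss <- sum(r^2)
  pen <- sum(pf * ((1 - alpha) / 2 * beta^2 + alpha * beta))
  structure(list(
    beta = beta, beta_scaled = beta / problem$col_scale,
    alpha = alpha, lambda = lambda,
    residue = rss, objective = rss + lambda * pen,
    converged = converged,
    failed = beta[problem$main_col] == 0,
    provenance = problem$provenance, ion_mz = problem$ion_mz
  ), class = "ms2_deconvolution")
}

#' @export
print.ms2_deconvolution <- function(x, ...) {
  cat(sprintf("<ms2_deconvolution> alpha=%.1f lambda=%.4g RSS=%.4g%s\n",
              x$alpha, x$lambda, x$residue,
              if (x$failed) " [FAILED: main-ion beta = 0]" else ""))
  df <- data.frame(ion_mz = round(x$ion_mz, 4), class = x$provenance,
                   beta = signif(x$beta, 5))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ms2_deconvolution <- function(object, scaled = FALSE, ...) {
  b <- if (scaled) object$beta_scaled else object$beta
  stats::setNames(b, paste0(object$provenance, "@", round(object$ion_mz, 4)))
}

#' Auto-tune (alpha, lambda) over the 110-point grid
#'
#' Evaluates all combinations of 11 alpha values (0 to 1 by 0.1) and 10
#' lambda values log-spaced over three decades down from
#' `lambda_max = max_j |x_j' y| / n` (the largest column-response
#' correlation), 110 solutions in total; the one with minimal unpenalized
#' RSS is returned. Ties prefer the sparser fit: larger lambda, then larger
#' alpha.
#'
#' @param problem an `ms2_deconv_problem`.
#' @param n_lambda,lambda_decades grid geometry (defaults 10 points over 3
#'   decades).
#' @return the winning `ms2_deconvolution`, with the full grid summary in
#'   attribute `grid` (data frame alpha, lambda, residue, objective) and the
#'   evaluated solution count in attribute `n_evaluated`.
#' @export
grid_optimize <- function(problem, n_lambda = 10, lambda_decades = 3) {
  alphas <- seq(0, 1, by = 0.1)
  n <- length(problem$y)
  lambda_max <- max(abs(crossprod(problem$X, problem$y))) / n
  if (lambda_max <= 0) lambda_max <- 1
  lambdas <- 10^seq(log10(lambda_max), log10(lambda_max) - lambda_decades,
                    length.out = n_lambda)
  sols <- vector("list", length(alphas) * length(lambdas))
  grid <- data.frame(alpha = numeric(0), lambda = numeric(0),
                     residue = numeric(0), objective = numeric(0))
  k <- 0L
  best <- NULL
  for (a in alphas) {
    for (l in lambdas) {
      k <- k + 1L
      sol <- solve_elastic_net(problem, a, l)
      sols[[k]] <- sol
      grid[k, ] <- c(a, l, sol$residue, sol$objective)
      if (is.null(best) ||
          sol$residue < best$residue ||
          (sol$residue == best$residue &&
             (sol$lambda > best$lambda ||
                (sol$lambda == best$lambda && sol$alpha > best$alpha)))) {
        best <- sol
      }
    }
  }
  attr(best, "grid") <- grid
  attr(best, "n_evaluated") <- k
  best
}

#' Subtract contaminant contributions from Spectrum 0
#'
#' Per axis bin, the contaminant contribution is the fitted sum over
#' non-MAIN columns; the remainder `max(0, y - contribution)` is floored at
#' `floor` of its own base peak, normalized, and returned. Deconvolution
#' fails (and Spectrum 0 is returned unchanged, flagged) when the main-ion
#' coefficient is zero or no fragment survives.
#'
#' @param spectrum0 the chimeric `ms2_spectrum`.
#' @param problem the `ms2_deconv_problem` built from it.
#' @param solution an `ms2_deconvolution` for the same problem.
#' @param floor relative intensity floor (fraction of the post-subtraction
#'   base peak) below which bins are dropped.
#' @return list `(spectrum, failed)`.
#' @export
subtract_contaminants <- function(spectrum0, problem, solution, floor = 0.005) {
  contam_cols <- which(problem$provenance != "MAIN")
  contribution <- if (length(contam_cols)) {
    as.numeric(problem$X[, contam_cols, drop = FALSE] %*%
                 solution$beta[contam_cols])
  } else rep(0, length(problem$y))
  remaining <- pmax(0, problem$y - contribution)
  if (solution$beta[problem$main_col] == 0 || max(remaining) <= 0) {
    return(list(spectrum = normalize_spectrum(spectrum0), failed = TRUE))
  }
  keep <- remaining >= floor * max(remaining)
  if (!any(keep)) {
    return(list(spectrum = normalize_spectrum(spectrum0), failed = TRUE))
  }
  out <- spectrum(problem$axis[keep], remaining[keep],
                  precursor_mz = spectrum0$precursor_mz,
                  precursor_rt = spectrum0$precursor_rt,
                  polarity = spectrum0$polarity,
                  source_id = spectrum0$source_id)
  list(spectrum = normalize_spectrum(out), failed = FALSE)
}

#' Deconvolve one DDA feature end to end
#'
#' Orchestrates chimera assessment, candidate assembly (classes I to IV),
#' design-matrix construction, grid-tuned elastic-net solving and
#' contaminant subtraction. Clean spectra bypass the regression and are
#' returned normalized.
#'
#' @param feature one row of an `ms1_features` table.
#' @param run the `ms2_run`.
#' @param library an open `ms2_library`, or `NULL`.
#' @param ppm_tol,rt_tol assignment tolerances.
#' @param mz_tol fragment alignment tolerance (Th).
#' @param intensity_threshold chimera acquisition threshold.
#' @param similarity similarity method for candidate selection.
#' @param floor post-subtraction relative intensity floor.
#' @param deconvolve set `FALSE` to skip the regression and return the
#'   merged spectrum as-is (the "non-deconvolved" arm).
#' @return list `(spectrum, is_chimeric, failed, assessment, solution)`;
#'   `NULL` when no MS2 scan is assigned to the feature.
#' @export
deconvolve_dda <- function(feature, run, library = NULL, ppm_tol = 10,
                           rt_tol = 15, mz_tol = 0.01,
                           intensity_threshold = 1e4,
                           similarity = "dot_product", floor = 0.005,
                           deconvolve = TRUE) {
  feats <- if (inherits(feature, "ms1_features")) feature else
    ms1_features(feature$mz_med, feature$rt_med, feature$mz_min,
                 feature$mz_max, feature$rt_min, feature$rt_max,
                 feature$intensity, feature$feature_id)
  assigned <- assign_ms2_to_features(run, feats, ppm_tol, rt_tol)[[1]]
  if (!length(assigned)) {
    message("no MS2 scan assigned to feature ", feats$feature_id[1])
    return(NULL)
  }
  spectrum0 <- merge_coassigned_spectra(assigned, mz_tol)
  assessment <- assess_chimeric(feats[1, ], spectrum0, run,
                                intensity_threshold)
  if (!assessment$is_chimeric || !deconvolve) {
    return(list(spectrum = normalize_spectrum(spectrum0),
                is_chimeric = assessment$is_chimeric, failed = FALSE,
                assessment = assessment, solution = NULL))
  }
  cands <- assemble_candidates(assessment, run, library, ppm_tol, similarity,
                               rt_cap = 2 * rt_tol, intensity_threshold)
  if (length(cands) < 2L) {
    # no contaminant got a candidate: nothing to subtract
    return(list(spectrum = normalize_spectrum(spectrum0), is_chimeric = TRUE,
                failed = TRUE, assessment = assessment, solution = NULL))
  }
  problem <- build_design_matrix(spectrum0, cands, mz_tol)
  solution <- grid_optimize(problem)
  sub <- subtract_contaminants(spectrum0, problem, solution, floor)
  list(spectrum = sub$spectrum, is_chimeric = TRUE, failed = sub$failed,
       assessment = assessment, solution = solution)
}
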