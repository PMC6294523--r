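#' Bonferroni adjustment against an explicit test count
#'
#' `min(1, p * m)` elementwise. `m` defaults to the vector length but can be
#' larger (e.g. the number of cis SNPs when only a subset of p-values is
#' passed, or an effective number of tests).
#'
#' @param p p-values in `(0, 1]`.
#' @param m number of tests (> 0; may be non-integer for effective-test
#'   corrections).
#' @return adjusted p-values.
#' @export
adjust_bonferroni <- function(p, m = length(p)) {
  if (length(m) != 1 || !is.finite(m) || m <= 0)
    stop("m must be a single positive number")
  pmin(1, p * m)
}

#' Benjamini-Hochberg and Benjamini-Yekutieli step-up adjustments
#'
#' Standard step-up adjusted p-values with monotonicity enforcement
#' (delegated to [stats::p.adjust()]); BY multiplies by the harmonic-sum
#' factor to remain valid under arbitrary dependence.
#'
#' @param p p-values in `(0, 1]`.
#' @return adjusted p-values (empty input gives an empty result).
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")

#' @rdname adjust_bh
#' @export
adjust_by <- function(p) stats::p.adjust(p, method = "BY")

#' Estimate the proportion of true null hypotheses (pi0)
#'
#' Storey-Tibshirani estimator: for each lambda on the grid,
#' `pi0(lambda) = mean(p > lambda) / (1 - lambda)`; the sequence is smoothed
#' with a cubic smoothing spline (df = 3) and evaluated at the largest lambda.
#' The estimate is clipped to `[pi0_floor, 1]`; a warning is issued when it
#' hits the floor (all p-values near zero) or when fewer than 100 p-values are
#' supplied.
#'
#' @param p p-values in `(0, 1]`.
#' @param lambda_grid tuning grid (default 0.05 to 0.90 step 0.05).
#' @param pi0_floor lower clip for the estimate (default 1e-3).
#' @return pi0 estimate in `(0, 1]`.
#' @export
estimate_pi0 <- function(p, lambda_grid = seq(0.05, 0.90, by = 0.05),
                         pi0_floor = 1e-3) {
  if (length(p) < 100)
    warning("pi0 estimation is unreliable with fewer than 100 p-values")
  pi0_l <- vapply(lambda_grid, function(l) mean(p > l) / (1 - l), numeric(1))
  pi0 <- if (length(lambda_grid) >= 4) {
    fit <- stats::smooth.spline(lambda_grid, pi0_l, df = 3)
    stats::predict(fit, x = max(lambda_grid))$y
  } else pi0_l[length(pi0_l)]
  if (pi0 < pi0_floor) {
    warning(sprintf("pi0 estimate %.2g floored at %g", pi0, pi0_floor))
    pi0 <- pi0_floor
  }
  min(pi0, 1)
}

#' Storey-Tibshirani q-values
#'
#' `q = pi0 * BH-adjusted p` with step-up monotonicity, so q-values are never
#' larger than the corresponding BH-adjusted p-values.
#'
#' @inheritParams estimate_pi0
#' @param pi0 optionally override the estimated pi0.
#' @return q-values in `(0, 1]`.
#' @export
adjust_st <- function(p, lambda_grid = seq(0.05, 0.90, by = 0.05),
                      pi0 = NULL) {
  if (!length(p)) return(numeric(0))
  if (is.null(pi0)) pi0 <- estimate_pi0(p, lambda_grid)
  pmin(1, pi0 * adjust_bh(p))
}

# Dispatch a pooled/global correction by method name.
adjust_method <- function(p, method, m = length(p)) {
  switch(method,
         bonferroni = adjust_bonferroni(p, m),
         bh = adjust_bh(p),
         by = adjust_by(p),
         st = adjust_st(p),
         stop(sprintf("unknown correction method '%s'", method)))
}
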