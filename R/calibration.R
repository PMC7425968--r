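#' Dispersal-kernel rate from movement distances
#'
#' Maximum-likelihood estimate of the exponential dispersal-kernel rate
#' `alpha` from observed inter-patch movement distances: the reciprocal of
#' the mean distance travelled. Outlier handling (e.g. dropping a single
#' long-distance disperser) is the caller's responsibility; the estimator
#' takes the distances as given and returns the unrounded MLE.
#'
#' @param distances Movement distances in meters, all > 0, nonempty.
#' @return `alpha` in 1/m.
#' @examples
#' alpha_mle(c(100, 150, 200)) # 1/150
#' @export
alpha_mle <- function(distances) {
  if (length(distances) == 0 || any(distances <= 0) || anyNA(distances)) {
    rlang::abort("`distances` must be a nonempty vector of positive distances",
                 class = "marshpva_bad_param")
  }
  1 / mean(distances)
}

#' Growth rate from the finite rate of increase
#'
#' Converts a finite (per-step multiplicative) rate of increase `lambda`
#' into the instantaneous per-capita growth rate `r_d = ln(lambda)`.
#'
#' @param lam Finite rate of increase, > 0. Vectorized.
#' @return `r_d` (log scale; 0 for a stationary population).
#' @examples
#' rd_from_lambda(c(0.5, 1, 2.3))
#' @export
rd_from_lambda <- function(lam) {
  if (any(lam <= 0) || anyNA(lam)) {
    rlang::abort("`lam` must be > 0", class = "marshpva_bad_param")
  }
  log(lam)
}

#' Carrying-capacity density by regression through the origin
#'
#' Regresses observed subpopulation sizes on habitat volume (water depth x
#' area, in cm x ha) with no intercept — a patch with no habitat holds no
#' animals — giving the density `k_volume` in voles/(cm x ha):
#' `slope = sum(N * V) / sum(V^2)`. The R-squared reported is for the
#' no-intercept model (proportion of uncentered sum of squares explained).
#'
#' @param n_values Observed subpopulation sizes, one per patch.
#' @param volumes Habitat volumes (cm x ha), same length, not all zero.
#' @return A one-row tibble: `slope` (the `k_volume` estimate),
#'   `r_squared`, `n`.
#' @examples
#' fit_k_volume(c(17, 34, 51), c(1, 2, 3)) # slope 17, perfect fit
#' @export
fit_k_volume <- function(n_values, volumes) {
  if (length(n_values) != length(volumes) || length(volumes) < 2) {
    rlang::abort("`n_values` and `volumes` must have equal length >= 2",
                 class = "marshpva_bad_param")
  }
  if (all(volumes == 0)) {
    rlang::abort("`volumes` must not be all zero",
                 class = "marshpva_bad_param")
  }
  fit <- stats::lm(n_values ~ volumes + 0)
  slope <- unname(stats::coef(fit)[1])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum(n_values^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  tibble::tibble(slope = slope, r_squared = r2, n = length(volumes))
}
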