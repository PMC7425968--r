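#' Migration pressure on every patch
#'
#' Expected number of immigrants per year into each patch:
#' `lambda_i = beta * sum_{j != i} N_j * exp(-alpha * d_ij)`.
#' Each patch feels pressure from all other patches, discounted by an
#' exponential dispersal kernel with rate `alpha` (the inverse mean
#' dispersal distance) and scaled by the calibrator `beta`. A patch's own
#' population never contributes to its own pressure, so a single-patch
#' landscape always has `lambda = 0`.
#'
#' @param n Vector of per-patch population sizes, >= 0.
#' @param d Symmetric distance matrix (m) matching `n` in order.
#' @param params A [migration_params()] object.
#' @return Vector of `lambda_i` (expected immigrants/yr), one per patch.
#' @examples
#' d <- matrix(c(0, 100, 100, 0), 2)
#' migration_pressure(c(200, 0), d, migration_params(alpha = 0.01, beta = 0.01))
#' @export
migration_pressure <- function(n, d, params = migration_params()) {
  if (any(n < 0)) {
    rlang::abort("population sizes must be >= 0", class = "marshpva_bad_param")
  }
  stopifnot(length(n) == nrow(d), nrow(d) == ncol(d))
  kernel <- exp(-params$alpha * d)
  diag(kernel) <- 0
  unname(drop(params$beta * (kernel %*% n)))
}

#' Draw immigrant counts
#'
#' Realizes migration pressure as independent Poisson draws, one per patch:
#' immigrants into patch i are `Poisson(lambda_i)`. Immigrants are added to
#' the receiving patch; source patches are not decremented.
#'
#' @param lambdas Vector of migration pressures, all >= 0.
#' @return Integer vector of immigrant counts.
#' @export
draw_migrants <- function(lambdas) {
  if (any(lambdas < 0)) {
    rlang::abort("`lambdas` must be >= 0", class = "marshpva_bad_param")
  }
  stats::rpois(length(lambdas), lambdas)
}
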