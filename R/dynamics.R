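#' One year of Ricker growth
#'
#' Advances population size one year under the stochastic Ricker recursion
#' `N' = N * exp(r_d * (1 - N/K) + eps)`. All arguments are vectorized over
#' patches. A patch with `K = 0` (no habitat) returns 0: it supports no
#' subpopulation, and the recursion's density term is undefined there.
#'
#' @param n Current population size(s), >= 0 (continuous; individuals).
#' @param k Carrying capacity(ies), >= 0.
#' @param r_d Per-capita growth rate at low density.
#' @param eps Environmental noise draw(s) added to the exponent. Default 0.
#' @return Population size(s) after one year; nonnegative, real-valued.
#' @examples
#' ricker_step(100, 100, 0.5)        # at K: stays at 100
#' ricker_step(50, 100, 0.01)        # 50 * exp(0.005)
#' @export
ricker_step <- function(n, k, r_d, eps = 0) {
  if (any(n < 0)) rlang::abort("`n` must be >= 0", class = "marshpva_bad_param")
  if (any(k < 0)) rlang::abort("`k` must be >= 0", class = "marshpva_bad_param")
  out <- ifelse(k == 0, 0, n * exp(r_d * (1 - n / pmax(k, .Machine$double.eps)) + eps))
  unname(out)
}

#' Draw environmental noise for all patches
#'
#' Draws one year of environmental stochasticity: a multivariate normal
#' vector with mean 0 and per-patch variance `v_r`. With `spacecor = 0`
#' (the default) draws are independent across patches. With `spacecor > 0`
#' the pairwise correlation between patches i and j is
#' `spacecor * exp(-d_ij / L)`, where `L` is the mean off-diagonal
#' inter-patch distance, so correlation decays with distance on the
#' landscape's own scale and `spacecor = 1` gives strong local correlation.
#'
#' If the implied correlation matrix is not positive semidefinite it is
#' repaired to the nearest PSD matrix (with unit diagonal) and a warning is
#' issued.
#'
#' @param n_patches Number of patches.
#' @param v_r Noise variance, >= 0.
#' @param spacecor Spatial correlation strength in \[0, 1\].
#' @param d Distance matrix (m), required when `spacecor > 0`.
#' @return A numeric vector of length `n_patches`.
#' @export
draw_noise <- function(n_patches, v_r, spacecor = 0, d = NULL) {
  if (v_r < 0) rlang::abort("`v_r` must be >= 0", class = "marshpva_bad_param")
  if (v_r == 0) return(numeric(n_patches))
  if (spacecor == 0 || n_patches == 1) {
    return(stats::rnorm(n_patches, 0, sqrt(v_r)))
  }
  stopifnot(!is.null(d), nrow(d) == n_patches, ncol(d) == n_patches)
  corr <- noise_correlation(d, spacecor)
  ch <- tryCatch(chol(corr), error = function(e) NULL)
  z <- stats::rnorm(n_patches)
  if (!is.null(ch)) {
    return(drop(crossprod(ch, z)) * sqrt(v_r))
  }
  # Singular or indefinite correlation (e.g. coincident patches at full
  # spacecor): repair to the nearest PSD correlation and sample by eigen
  # square root, which tolerates zero eigenvalues.
  ev <- eigen(corr, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    rlang::warn("noise correlation matrix not positive semidefinite; repaired to nearest PSD")
    corr <- as.matrix(Matrix::nearPD(corr, corr = TRUE)$mat)
    ev <- eigen(corr, symmetric = TRUE)
  }
  a <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  drop(a %*% z) * sqrt(v_r)
}

noise_correlation <- function(d, spacecor) {
  off <- d[upper.tri(d)]
  scale_len <- if (length(off) > 0 && mean(off) > 0) mean(off) else 1
  corr <- spacecor * exp(-d / scale_len)
  diag(corr) <- 1
  corr
}

#' Apply the local-extinction rule
#'
#' A subpopulation smaller than one individual is extinct: every entry of
#' `n` strictly below 1 is set to exactly 0; entries >= 1 are unchanged.
#'
#' @param n Vector of per-patch population sizes.
#' @return The thresholded vector.
#' @examples
#' apply_extinction(c(0.3, 1, 57.2)) # 0, 1, 57.2
#' @export
apply_extinction <- function(n) {
  ifelse(n < 1, 0, n)
}
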