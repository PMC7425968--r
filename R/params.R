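#' Demographic parameters
#'
#' Parameters of within-patch Ricker dynamics and environmental
#' stochasticity.
#'
#' @param r_d Per-capita instantaneous growth rate at low density
#'   (per vole per year). Default 0.01.
#' @param v_r Variance of environmental stochasticity, the additive normal
#'   noise on the Ricker exponent ((vole x yr)^2). Default 1. Must be >= 0.
#' @param spacecor Degree to which environmental noise co-varies between
#'   nearby patches, in \[0, 1\]. 0 (the default) gives independent
#'   per-patch noise; 1 gives strong local correlation. See [draw_noise()]
#'   for the correlation model.
#' @param k_volume Carrying-capacity density in voles per (cm x ha);
#'   `K_i = depth_cm * area_ha * k_volume`. Default 17.
#' @param ceiling Population ceiling as a multiple of K, applied after each
#'   Ricker step: a boom year cannot push a subpopulation above
#'   `ceiling * K`. The default 1 holds subpopulations at or below carrying
#'   capacity, in the tradition of ceiling-type PVA models; without a bound
#'   the weakly damped recursion (small `r_d`, `v_r` near 1) lets surviving
#'   patches drift orders of magnitude above K, which no field system of
#'   this kind exhibits. Set to `Inf` for the unbounded recursion.
#' @return A list of class `demography_params`.
#' @export
demography_params <- function(r_d = 0.01, v_r = 1, spacecor = 0,
                              k_volume = 17, ceiling = 1) {
  if (v_r < 0) rlang::abort("`v_r` must be >= 0", class = "marshpva_bad_param")
  if (spacecor < 0 || spacecor > 1) {
    rlang::abort("`spacecor` must be in [0, 1]", class = "marshpva_bad_param")
  }
  if (k_volume < 0) {
    rlang::abort("`k_volume` must be >= 0", class = "marshpva_bad_param")
  }
  if (ceiling < 1) {
    rlang::abort("`ceiling` must be >= 1", class = "marshpva_bad_param")
  }
  structure(list(r_d = r_d, v_r = v_r, spacecor = spacecor,
                 k_volume = k_volume, ceiling = ceiling),
            class = "demography_params")
}

#' Migration parameters
#'
#' @param alpha Rate of the exponential dispersal kernel: the inverse of
#'   the mean dispersal distance, in 1/m. Default 0.01.
#' @param beta Dimensionless migration calibrator scaling overall migration
#'   intensity; near 1 for vagile, locally common species, much lower for
#'   rare or dispersal-limited ones. Default 0.01.
#' @return A list of class `migration_params`.
#' @export
migration_params <- function(alpha = 0.01, beta = 0.01) {
  if (alpha < 0 || beta < 0) {
    rlang::abort("`alpha` and `beta` must be >= 0",
                 class = "marshpva_bad_param")
  }
  structure(list(alpha = alpha, beta = beta), class = "migration_params")
}

#' Simulation run configuration
#'
#' @param tmax Years per Monte-Carlo trial. Default 101.
#' @param trials Number of independent trials. Default 500.
#' @param seed Base RNG seed; trial `i` uses `seed + i - 1`, so results are
#'   reproducible and stable under partitioning of the trial set.
#' @param n0_rule Initialization rule for patch populations: `"at_K"`
#'   (default) starts every patch at its carrying capacity
#'   `depth * area * k_volume`; `"area_K"` starts at `area * k_volume`
#'   (a depth-free variant some incidence-function implementations use).
#' @param n0 Optional explicit vector of initial populations (one per
#'   patch, in landscape order), overriding `n0_rule` — useful for
#'   colonization experiments that seed some patches empty.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(tmax = 101, trials = 500, seed = 1,
                       n0_rule = c("at_K", "area_K"), n0 = NULL) {
  stopifnot(tmax >= 1, trials >= 1)
  n0_rule <- match.arg(n0_rule)
  if (!is.null(n0) && any(n0 < 0)) {
    rlang::abort("`n0` must be >= 0", class = "marshpva_bad_param")
  }
  structure(list(tmax = as.integer(tmax), trials = as.integer(trials),
                 seed = as.integer(seed), n0_rule = n0_rule, n0 = n0),
            class = "sim_config")
}

initial_population <- function(land, demo, config) {
  if (!is.null(config$n0)) {
    stopifnot(length(config$n0) == nrow(land))
    n0 <- config$n0
    names(n0) <- land$id
    return(n0)
  }
  switch(config$n0_rule,
         at_K = carrying_capacity(land, demo$k_volume),
         area_K = {
           n0 <- land$area_ha * demo$k_volume
           names(n0) <- land$id
           n0
         })
}
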