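#' Run one Monte-Carlo trial
#'
#' Simulates one trial of `config$tmax` years. Each year, in order: (1) a
#' shared environmental-noise vector is drawn, (2) every patch advances one
#' Ricker step simultaneously, capped at the ceiling `demo$ceiling * K`
#' (see [demography_params()]), (3) subpopulations below one individual go
#' locally extinct, (4) migration pressures are computed from the
#' post-growth populations, (5) Poisson immigrant counts are drawn and
#' added, and (6) the state is recorded. Populations are initialized by
#' `config$n0_rule` (default: at carrying capacity) and thresholded by the
#' extinction rule before year one.
#'
#' Patches whose carrying capacity is zero still receive immigrants (they
#' are counted in the migrant accounting and in that year's population) but
#' the immigrants die at the next growth step, so such patches act as
#' dispersal dead-ends, never as sources.
#'
#' @param land A [landscape()].
#' @param demo A [demography_params()] object.
#' @param mig A [migration_params()] object.
#' @param config A [sim_config()] object (its `trials` field is ignored
#'   here; one trial is run).
#' @param trial_seed Integer seed for this trial; the same seed reproduces
#'   the trial exactly.
#' @return A list of class `pva_trial` with elements `N` (a
#'   `(tmax + 1) x n_patches` matrix, row 1 the initial state), `migrants`
#'   (a `tmax x n_patches` integer matrix), and `extinct_year` (first year
#'   the metapopulation total hit zero, or `NA` if it survived to `tmax`).
#' @export
run_trial <- function(land, demo = demography_params(),
                      mig = migration_params(), config = sim_config(),
                      trial_seed = config$seed) {
  land <- landscape(land)
  d <- patch_distances(land)
  k <- unname(carrying_capacity(land, demo$k_volume))
  kernel <- migration_kernel(d, mig)
  withr_seed(trial_seed, simulate_trial(land, demo, mig, config, k, d, kernel))
}

# Inner loop; assumes RNG state already set and inputs validated.
simulate_trial <- function(land, demo, mig, config, k, d, kernel) {
  np <- nrow(land)
  tmax <- config$tmax
  n <- unname(initial_population(land, demo, config))
  n <- apply_extinction(n)
  N <- matrix(0, nrow = tmax + 1, ncol = np)
  migrants <- matrix(0L, nrow = tmax, ncol = np)
  N[1, ] <- n
  extinct_year <- NA_integer_
  cap <- demo$ceiling * k
  for (t in seq_len(tmax)) {
    eps <- draw_noise(np, demo$v_r, demo$spacecor, d)
    n <- ricker_step(n, k, demo$r_d, eps)
    if (is.finite(demo$ceiling)) n <- pmin(n, cap)
    n <- apply_extinction(n)
    m <- stats::rpois(np, mig$beta * drop(kernel %*% n))
    n <- n + m
    N[t + 1, ] <- n
    migrants[t, ] <- m
    if (sum(n) == 0) {
      extinct_year <- t
      break
    }
  }
  structure(list(N = N, migrants = migrants, extinct_year = extinct_year,
                 ids = land$id),
            class = "pva_trial")
}

migration_kernel <- function(d, mig) {
  kernel <- exp(-mig$alpha * d)
  diag(kernel) <- 0
  kernel
}

#' Run a Monte-Carlo simulation
#'
#' Runs `config$trials` independent trials (trial `i` is seeded with
#' `config$seed + i - 1`) and aggregates them into a summary: per-patch
#' yearly means and variances of population size, yearly occupancy
#' fractions, yearly metapopulation totals and migrant counts, per-trial
#' extinction years, and the mean time to extinction `T_e` (trials
#' surviving the full run are censored at `tmax`).
#'
#' @inheritParams run_trial
#' @return An object of class `pva_sim`; see [tidy.pva_sim()],
#'   [glance.pva_sim()], [response_variables()], [autoplot.pva_sim()].
#' @examples
#' land <- synthetic_landscape(seed = 1)
#' sim <- run_simulation(land, config = sim_config(trials = 20, seed = 1))
#' glance(sim)
#' @export
run_simulation <- function(land, demo = demography_params(),
                           mig = migration_params(), config = sim_config()) {
  land <- landscape(land)
  d <- patch_distances(land)
  k <- unname(carrying_capacity(land, demo$k_volume))
  kernel <- migration_kernel(d, mig)
  np <- nrow(land)
  tmax <- config$tmax
  trials <- config$trials

  sum_N <- matrix(0, tmax + 1, np)
  sum_N2 <- matrix(0, tmax + 1, np)
  sum_occ <- matrix(0, tmax + 1, np)
  trial_total_N <- matrix(0, trials, tmax + 1)
  trial_total_mig <- matrix(0, trials, tmax)
  trial_occ_frac <- matrix(0, trials, tmax + 1)
  extinct_years <- rep(NA_integer_, trials)

  for (i in seq_len(trials)) {
    tr <- withr_seed(config$seed + i - 1L,
                     simulate_trial(land, demo, mig, config, k, d, kernel))
    sum_N <- sum_N + tr$N
    sum_N2 <- sum_N2 + tr$N^2
    sum_occ <- sum_occ + (tr$N >= 1)
    trial_total_N[i, ] <- rowSums(tr$N)
    trial_total_mig[i, ] <- rowSums(tr$migrants)
    trial_occ_frac[i, ] <- rowMeans(tr$N >= 1)
    extinct_years[i] <- tr$extinct_year
  }

  mean_N <- sum_N / trials
  var_N <- if (trials > 1) (sum_N2 - trials * mean_N^2) / (trials - 1) else
    matrix(NA_real_, tmax + 1, np)
  var_N[var_N < 0] <- 0  # guard tiny negative rounding
  structure(list(
    mean_N = mean_N,
    var_N = var_N,
    occupancy = sum_occ / trials,
    trial_total_N = trial_total_N,
    trial_total_migrants = trial_total_mig,
    trial_occ_frac = trial_occ_frac,
    extinct_years = extinct_years,
    te = estimate_te(extinct_years, tmax),
    ids = land$id,
    demo = demo, mig = mig, config = config
  ), class = "pva_sim")
}

#' Mean time to extinction
#'
#' Mean over trials of the year the metapopulation first reached total size
#' zero. Trials that survive to the end of the run are censored: they
#' contribute `tmax`, never an extrapolation, so `T_e <= tmax` always.
#'
#' @param extinct_years Integer vector of per-trial extinction years, with
#'   `NA` marking censored (surviving) trials.
#' @param tmax Run length in years.
#' @return Mean time to extinction in years.
#' @examples
#' estimate_te(c(5, 10, NA), tmax = 101) # (5 + 10 + 101) / 3
#' @export
estimate_te <- function(extinct_years, tmax) {
  if (length(extinct_years) == 0) {
    rlang::abort("`extinct_years` must be nonempty",
                 class = "marshpva_bad_param")
  }
  yrs <- as.numeric(extinct_years)
  if (any(yrs < 1 | yrs > tmax, na.rm = TRUE)) {
    rlang::abort("extinction years must lie in 1..tmax",
                 class = "marshpva_bad_param")
  }
  yrs[is.na(yrs)] <- tmax
  mean(yrs)
}

#' Standard response variables of a simulation
#'
#' The four response variables used to compare scenarios: mean time to
#' extinction (`mvte`), and — at evaluation year `t`, by default 25 — the
#' mean proportion of occupied patches (`mvp`), mean metapopulation size
#' (`mN`), and mean number of migrants across patches (`mcol`).
#'
#' @param sim A `pva_sim` from [run_simulation()].
#' @param t Evaluation year, in `1..tmax`. Default 25.
#' @return A one-row tibble with columns `t`, `mvte`, `mvp`, `mN`, `mcol`.
#' @export
response_variables <- function(sim, t = 25) {
  stopifnot(inherits(sim, "pva_sim"))
  if (t < 1 || t > sim$config$tmax) {
    rlang::abort("`t` must be in 1..tmax", class = "marshpva_bad_param")
  }
  tibble::tibble(
    t = t,
    mvte = sim$te,
    mvp = mean(sim$trial_occ_frac[, t + 1]),
    mN = mean(sim$trial_total_N[, t + 1]),
    mcol = mean(sim$trial_total_migrants[, t])
  )
}
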