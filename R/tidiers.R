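#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation into a yearly table
#'
#' One row per year and patch: mean and variance of subpopulation size
#' across trials, and the fraction of trials in which the patch was
#' occupied (N >= 1).
#'
#' @param x A `pva_sim` from [run_simulation()].
#' @param ... Unused.
#' @return A tibble with columns `year`, `id`, `mean_N`, `var_N`,
#'   `occupancy`.
#' @method tidy pva_sim
#' @export
tidy.pva_sim <- function(x, ...) {
  years <- 0:x$config$tmax
  tidyr::expand_grid(year = years, id = x$ids) |>
    dplyr::mutate(
      mean_N = as.vector(t(x$mean_N)),
      var_N = as.vector(t(x$var_N)),
      occupancy = as.vector(t(x$occupancy))
    )
}

#' One-row summary of a simulation
#'
#' @param x A `pva_sim` from [run_simulation()].
#' @param t Evaluation year for the occupancy/abundance/migrant response
#'   variables; defaults to 25 or `tmax`, whichever is smaller.
#' @param ... Unused.
#' @return A one-row tibble: `trials`, `tmax`, `te`, `prop_extinct`,
#'   `mvp`, `mN`, `mcol`, `t`.
#' @method glance pva_sim
#' @export
glance.pva_sim <- function(x, t = min(25, x$config$tmax), ...) {
  rv <- response_variables(x, t)
  tibble::tibble(
    trials = x$config$trials,
    tmax = x$config$tmax,
    te = x$te,
    prop_extinct = mean(!is.na(x$extinct_years)),
    mvp = rv$mvp,
    mN = rv$mN,
    mcol = rv$mcol,
    t = t
  )
}

#' Yearly metapopulation trajectory table
#'
#' Across-trial means by year of the metapopulation total, migrants, and
#' proportion of occupied patches.
#'
#' @param sim A `pva_sim`.
#' @return A tibble with columns `year`, `mean_total_N`, `mean_migrants`
#'   (NA for year 0), `mean_prop_occupied`.
#' @export
trajectory <- function(sim) {
  stopifnot(inherits(sim, "pva_sim"))
  tibble::tibble(
    year = 0:sim$config$tmax,
    mean_total_N = colMeans(sim$trial_total_N),
    mean_migrants = c(NA_real_, colMeans(sim$trial_total_migrants)),
    mean_prop_occupied = colMeans(sim$trial_occ_frac)
  )
}

#' Plot a simulation's metapopulation trajectory
#'
#' Mean metapopulation size by year with a secondary occupancy panel.
#'
#' @param object A `pva_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pva_sim
#' @export
autoplot.pva_sim <- function(object, ...) {
  df <- trajectory(object) |>
    tidyr::pivot_longer(c("mean_total_N", "mean_prop_occupied"),
                        names_to = "measure", values_to = "value") |>
    dplyr::mutate(measure = dplyr::recode(.data$measure,
      mean_total_N = "Metapopulation size",
      mean_prop_occupied = "Proportion of patches occupied"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Year", y = NULL,
                  title = sprintf("Mean of %d trials; T_e = %.1f yr",
                                  object$config$trials, object$te)) +
    ggplot2::theme_minimal()
}

#' Plot a landscape map
#'
#' Patch centroids sized by carrying capacity and colored by group.
#'
#' @param object A `marsh_landscape`.
#' @param k_volume Carrying-capacity density used for sizing. Default 17.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot marsh_landscape
#' @export
autoplot.marsh_landscape <- function(object, k_volume = 17, ...) {
  df <- tibble::as_tibble(object)
  df$K <- carrying_capacity(object, k_volume)
  if (is.null(df$group)) df$group <- "all"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_m, y = .data$y_m,
                                   size = .data$K, color = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", size = "K (voles)",
                  color = "Region") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
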