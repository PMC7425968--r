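#' Read simulation parameters from a config file
#'
#' Reads a YAML or JSON file holding any of the model parameters
#' (`r_d`, `v_r`, `spacecor`, `k_volume`, `ceiling`, `alpha`, `beta`,
#' `tmax`, `trials`, `seed`, `n0_rule`); unlisted parameters keep their
#' defaults. Format is chosen by extension (`.json` vs `.yml`/`.yaml`).
#'
#' @param path Config file path.
#' @return A list with elements `demo` ([demography_params()]),
#'   `mig` ([migration_params()]), `config` ([sim_config()]).
#' @export
read_config <- function(path) {
  vals <- read_keyed_file(path)
  pick <- function(fn, keys) {
    args <- vals[intersect(keys, names(vals))]
    do.call(fn, args)
  }
  list(
    demo = pick(demography_params,
                c("r_d", "v_r", "spacecor", "k_volume", "ceiling")),
    mig = pick(migration_params, c("alpha", "beta")),
    config = pick(sim_config, c("tmax", "trials", "seed", "n0_rule"))
  )
}

#' Read scenario definitions from a file
#'
#' Reads a YAML or JSON file containing a list of scenarios, each a map
#' with a `name` and a list of `modifiers`; each modifier may have `ids`,
#' `region`, `action` and `magnitude` fields as in [modifier()]. A
#' scenario with no `modifiers` entry has none (e.g. the baseline).
#'
#' @param path Scenario file path.
#' @return A list of [scenario()] objects.
#' @export
read_scenarios <- function(path) {
  raw <- read_keyed_file(path)
  purrr::map(raw, function(s) {
    mods <- purrr::map(s$modifiers %||% list(), function(m) {
      modifier(ids = m$ids, region = m$region,
               action = m$action %||% "scale_depth",
               magnitude = m$magnitude %||% 1)
    })
    do.call(scenario, c(list(name = s$name), mods))
  })
}

read_keyed_file <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      rlang::abort("reading YAML requires the yaml package; use JSON instead")
    }
    yaml::read_yaml(path)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write simulation outputs to a directory
#'
#' Writes the standard output files of a run: `summary.csv` (yearly means
#' of metapopulation size, migrants and occupancy), `occupancy.csv`
#' (per-patch, per-year occupancy fractions), `extinction_years.csv`
#' (per-trial extinction year, censored trials marked), `response.json`
#' (the [response_variables()] record), and `params.json` echoing every
#' parameter of the run.
#'
#' @param sim A `pva_sim` from [run_simulation()].
#' @param dir Output directory, created if absent.
#' @param t Evaluation year for `response.json`. Default 25.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, t = min(25, sim$config$tmax)) {
  stopifnot(inherits(sim, "pva_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(trajectory(sim), file.path(dir, "summary.csv"))
  readr::write_csv(tidy(sim), file.path(dir, "occupancy.csv"))
  yrs <- sim$extinct_years
  readr::write_csv(
    tibble::tibble(trial = seq_along(yrs),
                   extinct_year = ifelse(is.na(yrs), sim$config$tmax, yrs),
                   censored = is.na(yrs)),
    file.path(dir, "extinction_years.csv"))
  rv <- response_variables(sim, t)
  jsonlite::write_json(
    list(mvte = rv$mvte, mvp = rv$mvp, mN = rv$mN, mcol = rv$mcol, t = t),
    file.path(dir, "response.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(demography = unclass(sim$demo), migration = unclass(sim$mig),
         run = unclass(sim$config)),
    file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
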