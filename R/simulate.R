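#' Run one replicate simulation
#'
#' Executes the full per-step cycle — invasion (once, if the scenario's
#' invasion flag is on), immigration, recruitment (from step 2), growth,
#' mortality — for `config$n_steps` steps, recording per-species biomass
#' and abundance at the thinned recording steps (always including steps
#' 5,000, 10,000 and the final step when in range). Fully reproducible
#' from `seed`.
#'
#' @param scenario A [psfi_scenario()] or scenario name string. The
#'   `invasion` flag of the scenario controls whether invaders are placed;
#'   parse names with `parse_scenario(name, invasion = TRUE)` or set
#'   `invasion = TRUE` here to override.
#' @param config A [sim_config()].
#' @param seed Integer seed; if non-`NULL`, `set.seed(seed)` is called.
#' @param invasion Optional logical overriding `scenario$invasion`.
#' @param table Optional pre-built `interaction_table` (rebuilt from the
#'   scenario when `NULL`).
#' @return A `psfi_sim` object: list with `scenario`, `config`, `seed`,
#'   `steps` (recorded step indices), `biomass` and `abundance` (matrices,
#'   recorded steps x species, invader in the last column), `final` (the
#'   final `psfi_grid`), and `invaders_placed`.
#' @examples
#' sim <- run_simulation("Null", sim_config(grid_side = 15, n_steps = 60,
#'                                          invasion_step = 50, thin = 10),
#'                       seed = 1, invasion = TRUE)
#' tail(sim$steps)
#' @export
run_simulation <- function(scenario, config = sim_config(), seed = NULL,
                           invasion = NULL, table = NULL) {
  if (is.character(scenario)) scenario <- parse_scenario(scenario)
  stopifnot(inherits(scenario, "psfi_scenario"),
            inherits(config, "sim_config"))
  if (!is.null(invasion)) scenario$invasion <- isTRUE(invasion)
  if (is.null(table))
    table <- build_interaction_table(scenario, config$n_resident_species)
  stopifnot(table$n_resident == config$n_resident_species)
  if (!is.null(seed)) set.seed(seed)
  steps <- record_steps(config)
  res <- cpp_run_simulation(
    config$grid_side, config$n_resident_species, lookup_matrix(table),
    config$p_immigration, config$p_mortality, config$n_steps,
    if (scenario$invasion) config$invasion_step else 0L,
    config$n_invaders, config$initial_biomass, config$neighbourhood_cap,
    config$toroidal, steps)
  species <- c(paste0("sp", seq_len(table$n_resident)), "invader")
  colnames(res$biomass) <- species
  colnames(res$abundance) <- species
  structure(
    list(scenario = scenario, config = config, seed = seed,
         steps = res$steps, biomass = res$biomass,
         abundance = res$abundance,
         final = as_grid(res$final, config$grid_side),
         invaders_placed = res$invaders_placed),
    class = "psfi_sim")
}

#' @export
print.psfi_sim <- function(x, ...) {
  cat("<psfi_sim> ", scenario_name(x$scenario),
      if (x$scenario$invasion) " (+invasion)" else "",
      "; ", x$config$n_steps, " steps; ", length(x$steps),
      " recorded\n", sep = "")
  invisible(x)
}

#' Community summary at a recorded step
#'
#' Per-species biomass and abundance vectors (residents plus invader) at
#' one recorded time step of a simulation.
#'
#' @param sim A `psfi_sim`.
#' @param step A recorded step index (see `sim$steps`).
#' @return A `community_summary`: list with `step`, `biomass`,
#'   `abundance` (named vectors over residents + invader), `n_resident`.
#' @export
community_summary <- function(sim, step) {
  stopifnot(inherits(sim, "psfi_sim"))
  k <- match(step, sim$steps)
  if (is.na(k))
    stop("step ", step, " was not recorded; recorded steps are in sim$steps",
         call. = FALSE)
  structure(
    list(step = step, biomass = sim$biomass[k, ],
         abundance = sim$abundance[k, ],
         n_resident = sim$config$n_resident_species),
    class = "community_summary")
}

#' @export
print.community_summary <- function(x, ...) {
  cat("<community_summary> step ", x$step, "; ",
      sum(x$abundance), " individuals; total biomass ",
      format(sum(x$biomass)), "\n", sep = "")
  invisible(x)
}

#' Export simulation output
#'
#' `write_timeseries()` writes the recorded per-species time series in long
#' tidy form (step, species, biomass, abundance). `write_final_state()`
#' writes the final-grid snapshot (cell, row, col, occupant, biomass,
#' soil).
#'
#' @param sim A `psfi_sim`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(sim, path) {
  species <- colnames(sim$biomass)
  df <- data.frame(
    step = rep(sim$steps, times = length(species)),
    species = rep(species, each = length(sim$steps)),
    biomass = as.vector(sim$biomass),
    abundance = as.vector(sim$abundance))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
write_final_state <- function(sim, path) {
  g <- sim$final
  n <- g$side^2
  df <- data.frame(
    cell = seq_len(n),
    row = rep(seq_len(g$side), each = g$side),
    col = rep(seq_len(g$side), times = g$side),
    occupant = g$occupant, biomass = g$biomass, soil = g$soil)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
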