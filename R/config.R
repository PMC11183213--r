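#' Simulation configuration
#'
#' All numeric parameters of the lattice simulation. Defaults are the study
#' conditions: a 100 x 100 grid, 100 resident species, per-empty-cell
#' immigration probability 0.001, per-individual mortality probability 0.1,
#' 12,000 time steps, invasion of 100 individuals at step 10,001, initial
#' biomass 1, and a combined focal-plus-neighbours biomass cap of 100.
#'
#' @param grid_side Side length of the square grid (cells).
#' @param n_resident_species Size of the resident species pool.
#' @param p_immigration Probability per empty cell per step of colonisation
#'   by a uniformly drawn resident species.
#' @param p_mortality Probability per individual per step of dying.
#' @param n_steps Number of time steps to simulate.
#' @param invasion_step Step at which invaders are placed (before that
#'   step's immigration). Only used when the scenario's invasion flag is on.
#' @param n_invaders Number of invader individuals to place.
#' @param initial_biomass Biomass of every new immigrant/recruit/invader.
#' @param neighbourhood_cap Maximum combined biomass of a plant and its von
#'   Neumann neighbours (up to five individuals). Sets the biomass scale
#'   only; relative growth-rate ratios drive the dynamics.
#' @param toroidal Logical; wrap grid edges (default hard edges).
#' @param thin Recording interval in steps. Steps 5,000, 10,000 and the
#'   final step are always recorded when within range.
#' @return A `sim_config` list.
#' @examples
#' sim_config(grid_side = 20, n_steps = 100, thin = 10)
#' @export
sim_config <- function(grid_side = 100, n_resident_species = 100,
                       p_immigration = 0.001, p_mortality = 0.1,
                       n_steps = 12000, invasion_step = 10001,
                       n_invaders = 100, initial_biomass = 1,
                       neighbourhood_cap = 100, toroidal = FALSE,
                       thin = 100) {
  stopifnot(grid_side >= 1, n_resident_species >= 1,
            p_immigration >= 0, p_immigration <= 1,
            p_mortality >= 0, p_mortality <= 1,
            n_steps >= 1, n_invaders >= 0, initial_biomass > 0,
            neighbourhood_cap > 0, thin >= 1)
  if (!is.na(invasion_step) && invasion_step > n_steps)
    stop("invasion_step must not exceed n_steps", call. = FALSE)
  structure(
    list(grid_side = as.integer(grid_side),
         n_resident_species = as.integer(n_resident_species),
         p_immigration = p_immigration, p_mortality = p_mortality,
         n_steps = as.integer(n_steps),
         invasion_step = as.integer(invasion_step),
         n_invaders = as.integer(n_invaders),
         initial_biomass = initial_biomass,
         neighbourhood_cap = neighbourhood_cap,
         toroidal = isTRUE(toroidal), thin = as.integer(thin)),
    class = "sim_config")
}

# steps at which per-species summaries are recorded
record_steps <- function(config) {
  s <- seq(config$thin, config$n_steps, by = config$thin)
  always <- c(5000L, 10000L, config$n_steps)
  if (!is.na(config$invasion_step)) always <- c(always, config$invasion_step)
  sort(unique(c(s, always[always >= 1L & always <= config$n_steps])))
}
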