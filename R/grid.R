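#' Grid state
#'
#' The lattice state: per cell, the occupant species (0 = empty), its
#' biomass (0 iff empty), its fixed establishment growth rate, and the
#' species that last conditioned the cell's soil (0 = never occupied).
#' [new_grid()] returns the start-of-simulation state: all cells empty,
#' all soils unconditioned.
#'
#' @param config A [sim_config()].
#' @return A `psfi_grid`: list with integer vectors `occupant`, `soil`,
#'   numeric vectors `biomass`, `growth_rate` (all of length
#'   `grid_side^2`, row-major), and `side`.
#' @export
new_grid <- function(config = sim_config()) {
  n <- config$grid_side^2
  structure(
    list(occupant = integer(n), biomass = numeric(n),
         growth_rate = numeric(n), soil = integer(n),
         side = config$grid_side),
    class = "psfi_grid")
}

#' @export
print.psfi_grid <- function(x, ...) {
  cat("<psfi_grid> ", x$side, "x", x$side, "; ", sum(x$occupant > 0),
      " occupied; total biomass ", format(sum(x$biomass)), "\n", sep = "")
  invisible(x)
}

as_grid <- function(state, side) {
  structure(c(state[c("occupant", "biomass", "growth_rate", "soil")],
              list(side = side)),
            class = "psfi_grid")
}

# rate-lookup matrix passed to the engine: one row per species, column 1 =
# unconditioned soil (standard), column j + 1 = soil conditioned by species j
lookup_matrix <- function(table) {
  cbind(rep(table$classes[["standard"]], table$invader), table$rates)
}

#' Single simulation processes
#'
#' One process applied once to a grid state, in the same implementation the
#' full engine uses. Within a time step the order is immigration,
#' recruitment, growth, mortality; the invasion event (when scheduled)
#' precedes immigration of its step.
#'
#' * `step_immigration()`: each empty cell is colonised with probability
#'   `p_immigration` by a uniformly drawn resident species (never the
#'   invader) at `initial_biomass`; its growth rate is set from the cell's
#'   soil by [establishment_rate()] and the soil becomes its species.
#' * `step_recruitment()`: every remaining empty cell receives one recruit
#'   whose species is drawn with probability proportional to current total
#'   species biomass (global dispersal); no-op if the community is empty.
#' * `step_growth()`: each plant's biomass is multiplied by its fixed rate,
#'   then clipped so the plant plus its (pre-step) von Neumann neighbours
#'   stay within `neighbourhood_cap`; clipping never reduces biomass below
#'   its pre-growth value.
#' * `step_mortality()`: each plant dies with probability `p_mortality`;
#'   its cell empties but keeps the dead plant's species as soil.
#' * `introduce_invader()`: places `min(n_invaders, empty cells)` invaders
#'   into distinct random empty cells; warns if the grid cannot hold them
#'   all.
#'
#' @param grid A `psfi_grid`.
#' @param config A [sim_config()].
#' @param table An `interaction_table` for the scenario.
#' @return The updated `psfi_grid`. `introduce_invader()` attaches the
#'   number placed as attribute `n_placed`.
#' @name simulation_steps
NULL

#' @rdname simulation_steps
#' @export
step_immigration <- function(grid, config, table) {
  st <- cpp_step_immigration(grid$occupant, grid$biomass, grid$growth_rate,
                             grid$soil, lookup_matrix(table),
                             config$p_immigration,
                             config$n_resident_species,
                             config$initial_biomass)
  as_grid(st, grid$side)
}

#' @rdname simulation_steps
#' @export
step_recruitment <- function(grid, config, table) {
  st <- cpp_step_recruitment(grid$occupant, grid$biomass, grid$growth_rate,
                             grid$soil, lookup_matrix(table),
                             config$initial_biomass)
  as_grid(st, grid$side)
}

#' @rdname simulation_steps
#' @export
step_growth <- function(grid, config) {
  st <- cpp_step_growth(grid$occupant, grid$biomass, grid$growth_rate,
                        grid$soil, grid$side, config$neighbourhood_cap,
                        config$toroidal)
  as_grid(st, grid$side)
}

#' @rdname simulation_steps
#' @export
step_mortality <- function(grid, config) {
  st <- cpp_step_mortality(grid$occupant, grid$biomass, grid$growth_rate,
                           grid$soil, config$p_mortality)
  as_grid(st, grid$side)
}

#' @rdname simulation_steps
#' @export
introduce_invader <- function(grid, config, table) {
  st <- cpp_introduce_invader(grid$occupant, grid$biomass, grid$growth_rate,
                              grid$soil, lookup_matrix(table),
                              config$n_invaders, config$initial_biomass)
  if (st$n_placed < config$n_invaders)
    warning("only ", st$n_placed, " of ", config$n_invaders,
            " invaders placed: not enough empty cells", call. = FALSE)
  out <- as_grid(st, grid$side)
  attr(out, "n_placed") <- st$n_placed
  out
}

#' Establishment growth rate of a recruit
#'
#' The per-step growth rate a recruit of species `recruit` establishes with
#' on soil last conditioned by species `soil` (0 = unconditioned, giving the
#' standard rate). The rate is fixed for the plant's lifetime.
#'
#' @param recruit Recruit species index.
#' @param soil Conditioning species index or 0.
#' @param table An `interaction_table`.
#' @return Numeric growth rate.
#' @export
establishment_rate <- function(recruit, soil, table) {
  interaction_rate(table, recruit, soil)
}
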