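# Small-scale configurations and states used across test files.

small_config <- function(...) {
  sim_config(grid_side = 20, n_steps = 200, invasion_step = 150,
             n_invaders = 20, thin = 50, ...)
}

# a grid populated deterministically: species cycle over cells, biomass
# drawn from the supplied RNG stream, soils match occupants
random_grid <- function(config, occupancy = 0.7, table = NULL) {
  g <- new_grid(config)
  n <- config$grid_side^2
  occ_cells <- which(stats::runif(n) < occupancy)
  sp <- ((occ_cells - 1L) %% config$n_resident_species) + 1L
  g$occupant[occ_cells] <- sp
  g$biomass[occ_cells] <- stats::runif(length(occ_cells), 0.5, 25)
  g$growth_rate[occ_cells] <- 1.65
  g$soil[occ_cells] <- sp
  g
}

# von Neumann neighbourhood sums (focal + up to 4 neighbours), brute force
nbhd_sums <- function(biomass, side, toroidal = FALSE) {
  m <- matrix(biomass, nrow = side, byrow = TRUE)
  out <- matrix(0, side, side)
  for (r in seq_len(side)) {
    for (c in seq_len(side)) {
      s <- m[r, c]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (toroidal) {
          rr <- ((rr - 1) %% side) + 1; cc <- ((cc - 1) %% side) + 1
          s <- s + m[rr, cc]
        } else if (rr >= 1 && rr <= side && cc >= 1 && cc <= side) {
          s <- s + m[rr, cc]
        }
      }
      out[r, c] <- s
    }
  }
  as.vector(t(out))
}

# count of directed non-standard heterospecific entries among residents
n_nonstandard_hetero <- function(table) {
  r <- table$rates[seq_len(table$n_resident), seq_len(table$n_resident)]
  std <- table$classes[["standard"]]
  sum(r != std) - sum(diag(r) != std)
}
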