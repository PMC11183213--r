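cfg <- small_config()
null_tab <- build_interaction_table("Null", cfg$n_resident_species)
nc_tab <- build_interaction_table("Null.NC", cfg$n_resident_species)

test_that("a new grid is empty and unconditioned", {
  g <- new_grid(cfg)
  expect_equal(sum(g$occupant > 0), 0)
  expect_equal(sum(g$soil > 0), 0)
  expect_equal(sum(g$biomass), 0)
})

test_that("immigration colonises empty cells with residents only", {
  set.seed(11)
  g <- new_grid(cfg)
  cfg_hi <- small_config(p_immigration = 0.5)
  g2 <- step_immigration(g, cfg_hi, null_tab)
  newc <- which(g2$occupant > 0)
  expect_gt(length(newc), 0)
  expect_true(all(g2$occupant[newc] <= cfg$n_resident_species))
  expect_true(all(g2$biomass[newc] == cfg$initial_biomass))
  expect_true(all(g2$soil[newc] == g2$occupant[newc]))
  # immigrants on unconditioned soil establish at the standard rate
  expect_true(all(g2$growth_rate[newc] == 1.65))
  # zero-probability limit leaves the state untouched
  g3 <- step_immigration(g, small_config(p_immigration = 0), null_tab)
  expect_identical(g3$occupant, g$occupant)
})

test_that("establishment rates follow the interaction table", {
  inv <- nc_tab$invader
  expect_equal(establishment_rate(inv, inv, nc_tab), 1.82)
  expect_equal(establishment_rate(inv, 7, nc_tab), 1.65)
  expect_equal(establishment_rate(3, 0, nc_tab), 1.65)
  expect_equal(establishment_rate(3, 3, nc_tab), 1.49)
  expect_equal(establishment_rate(3, 3, null_tab), 1.65)
  expect_error(establishment_rate(500, 0, nc_tab), "unknown")
  expect_error(establishment_rate(1, 500, nc_tab), "unknown")
})

test_that("recruitment fills empty cells in proportion to species biomass", {
  set.seed(21)
  g <- new_grid(cfg)
  # two-species community: biomass 30 vs 10 in two corners
  g$occupant[1] <- 1L; g$biomass[1] <- 30; g$growth_rate[1] <- 1.65
  g$soil[1] <- 1L
  g$occupant[2] <- 2L; g$biomass[2] <- 10; g$growth_rate[2] <- 1.65
  g$soil[2] <- 2L
  g2 <- step_recruitment(g, cfg, null_tab)
  expect_equal(sum(g2$occupant == 0), 0)  # all empties filled
  recruits <- g2$occupant[-(1:2)]
  expect_true(all(recruits %in% 1:2))
  frac1 <- mean(recruits == 1)
  expect_gt(frac1, 0.70); expect_lt(frac1, 0.80)  # around 0.75
  # recruiting into an empty community is a no-op
  g3 <- step_recruitment(new_grid(cfg), cfg, null_tab)
  expect_equal(sum(g3$occupant > 0), 0)
})

test_that("growth is multiplicative, capped against pre-step neighbours", {
  g <- new_grid(cfg)
  g$occupant[1] <- 1L; g$biomass[1] <- 1; g$growth_rate[1] <- 1.65
  g$soil[1] <- 1L
  g2 <- step_growth(g, cfg)
  expect_equal(g2$biomass[1], 1.65)  # isolated plant grows freely
  # a plant whose pre-step neighbourhood already meets the cap cannot grow
  side <- cfg$grid_side
  g$occupant[2] <- 2L; g$biomass[2] <- 60; g$growth_rate[2] <- 1.65
  g$soil[2] <- 2L
  g$occupant[side + 1] <- 3L; g$biomass[side + 1] <- 60
  g$growth_rate[side + 1] <- 1.65; g$soil[side + 1] <- 3L
  g3 <- step_growth(g, cfg)  # cell 1 has neighbour sum 120 > cap 100
  expect_equal(g3$biomass[1], 1)
})

test_that("the growth clip rule holds over random states", {
  set.seed(31)
  for (rep in 1:5) {
    g <- random_grid(cfg)
    pre <- g$biomass
    g2 <- step_growth(g, cfg)
    nb <- nbhd_sums(pre, cfg$grid_side) - pre  # neighbours only
    occ <- g$occupant > 0
    # never shrink; never exceed growth proposal; clip to pre-step room
    expect_true(all(g2$biomass[occ] >= pre[occ]))
    expect_true(all(g2$biomass[occ] <= pre[occ] * g$growth_rate[occ] + 1e-9))
    lim <- pmax(pre, cfg$neighbourhood_cap - nb)
    expect_true(all(g2$biomass[occ] <= lim[occ] + 1e-9))
    # biomass still zero iff empty
    expect_true(all((g2$biomass > 0) == occ))
  }
})

test_that("toroidal growth wraps neighbourhoods across edges", {
  cfg_t <- small_config(toroidal = TRUE)
  g <- new_grid(cfg_t)
  side <- cfg_t$grid_side
  # plant in a corner with a heavy neighbour wrapped to the far column
  g$occupant[1] <- 1L; g$biomass[1] <- 10; g$growth_rate[1] <- 1.65
  g$soil[1] <- 1L
  g$occupant[side] <- 2L; g$biomass[side] <- 95; g$growth_rate[side] <- 1.65
  g$soil[side] <- 2L
  flat <- step_growth(g, cfg_t)
  expect_equal(flat$biomass[1], 10)  # wrapped neighbour blocks growth
  hard <- step_growth(g, small_config())
  expect_equal(hard$biomass[1], 16.5)
})

test_that("mortality empties cells but keeps soil conditioning", {
  set.seed(41)
  g <- random_grid(cfg)
  occ_before <- g$occupant
  g2 <- step_mortality(g, small_config(p_mortality = 1))
  expect_equal(sum(g2$occupant > 0), 0)
  expect_identical(g2$soil, g$soil)  # previous-occupant effect persists
  died <- which(occ_before > 0)
  expect_true(all(g2$soil[died] == occ_before[died]))
  g3 <- step_mortality(g, small_config(p_mortality = 0))
  expect_identical(g3$occupant, g$occupant)
})

test_that("invaders are placed into distinct empty cells", {
  set.seed(51)
  g <- random_grid(cfg, occupancy = 0.5)
  empty_before <- which(g$occupant == 0)
  g2 <- introduce_invader(g, cfg, nc_tab)
  expect_equal(attr(g2, "n_placed"), cfg$n_invaders)
  placed <- which(g2$occupant == nc_tab$invader)
  expect_equal(length(placed), cfg$n_invaders)
  expect_true(all(placed %in% empty_before))
  # invader on resident-conditioned soil establishes at standard rate
  on_resident <- placed[g$soil[placed] %in% seq_len(100)]
  expect_true(all(g2$growth_rate[on_resident] == 1.65))
  # saturated grid: warn and place nobody
  full <- random_grid(cfg, occupancy = 1.01)
  expect_warning(g3 <- introduce_invader(full, cfg, nc_tab), "0 of")
  expect_equal(attr(g3, "n_placed"), 0)
})

test_that("simulations are reproducible and respect the invasion toggle", {
  s1 <- run_simulation("Null.NC", cfg, seed = 7, invasion = TRUE)
  s2 <- run_simulation("Null.NC", cfg, seed = 7, invasion = TRUE)
  expect_identical(s1$biomass, s2$biomass)
  expect_identical(s1$final$occupant, s2$final$occupant)
  s3 <- run_simulation("Null.NC", cfg, seed = 8, invasion = TRUE)
  expect_false(identical(s1$biomass, s3$biomass))
  no_inv <- run_simulation("Null.NC", cfg, seed = 7, invasion = FALSE)
  expect_true(all(no_inv$biomass[, "invader"] == 0))
  expect_true(all(no_inv$abundance[, "invader"] == 0))
  # invader absent before the invasion step, present at it
  pre <- s1$steps < cfg$invasion_step
  expect_true(all(s1$abundance[pre, "invader"] == 0))
})

test_that("state invariants hold along a full run", {
  sim <- run_simulation("Neg.Ring.5.NC", cfg, seed = 9, invasion = TRUE)
  g <- sim$final
  occ <- g$occupant > 0
  expect_true(all((g$biomass > 0) == occ))
  expect_true(all(g$biomass >= 0))
  # occupied cells condition their own soil
  expect_true(all(g$soil[occ] == g$occupant[occ]))
  # every occupant rate is one of the scenario's classes
  expect_true(all(g$growth_rate[occ] %in% c(1.49, 1.65, 1.82)))
  # abundance/biomass consistency in the recorded series
  expect_true(all((sim$abundance > 0) == (sim$biomass > 0)))
})

test_that("an empty world without immigration stays empty", {
  cfg0 <- small_config(p_immigration = 0)
  sim <- run_simulation("Null", cfg0, seed = 3, invasion = FALSE)
  expect_equal(sum(sim$biomass), 0)
  expect_equal(sum(sim$final$occupant), 0)
})

test_that("unconditioned soil count is non-increasing over a run", {
  set.seed(61)
  g <- new_grid(cfg)
  tab <- null_tab
  uncond <- sum(g$soil == 0)
  for (t in 1:30) {
    g <- step_immigration(g, cfg, tab)
    if (t >= 2) g <- step_recruitment(g, cfg, tab)
    g <- step_growth(g, cfg)
    g <- step_mortality(g, cfg)
    u <- sum(g$soil == 0)
    expect_lte(u, uncond)
    uncond <- u
  }
})

test_that("species labels are exchangeable under relabelling", {
  # permuting species labels in a modular table yields the same table when
  # the permutation maps modules onto modules
  tab <- build_modular(100, 5, "negative")
  perm <- c(6:10, 1:5, 11:100)  # swap modules 1 and 2
  permuted <- tab$rates[1:100, 1:100][perm, perm]
  expect_equal(unname(permuted), unname(tab$rates[1:100, 1:100]))
})

test_that("simulation export files round-trip", {
  sim <- run_simulation("Null", cfg, seed = 2, invasion = TRUE)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_timeseries(sim, f1)
  ts <- read.csv(f1)
  expect_equal(nrow(ts), length(sim$steps) * 101)
  expect_equal(sum(ts$biomass), sum(sim$biomass))
  write_final_state(sim, f2)
  fs <- read.csv(f2)
  expect_equal(nrow(fs), cfg$grid_side^2)
  expect_equal(sum(fs$biomass), sum(sim$final$biomass))
})
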