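# psfisim

Stochastic lattice simulation of plant communities structured by
plant-soil feedback interaction (PSFI) networks, and of their vulnerability
to invasion.

Every plant on a 100 x 100 grid conditions the soil of its cell; the
conditioning species sets the growth rate — slow (1.49), standard (1.65)
or fast (1.82) per time step — with which the cell's *next* occupant
establishes. Communities assemble from an empty grid through immigration
(probability 0.001 per empty cell per step from a 100-species pool),
biomass-weighted global recruitment, multiplicative growth capped by the
combined biomass of a plant and its four neighbours, and mortality
(probability 0.1 per individual per step). Heterospecific feedback
networks with **modular**, **nested** or **intransitive ring**
architecture (group sizes 5/10/20, positive or negative effects), with or
without **negative conspecific feedback**, give 38 scenarios; each can be
run with or without an invasion event in which 100 individuals of a
non-interacting invader with positive conspecific feedback are placed at
step 10,001 of 12,000.

Per replicate the package reports:

- **invasibility** — the invader's % of total biomass at the final step;
- **pre-invasion diversity** — inverse Simpson \(1/D = 1/\sum_i p_i^2\)
  on resident biomass shares at step 10,000;
- **compositional change** — Bray-Curtis distance
  \(\sum|x_i-y_i| / \sum(x_i+y_i)\) between resident biomass at steps
  5,000 and 10,000;
- **productivity** — the resident community's expected establishment rate
  \(\sum_i\sum_j p_i p_j\, r(i,j)\) from species frequencies at step
  10,000.

It is aimed at ecologists studying how interaction-network architecture
shapes coexistence, diversity and invasion resistance in simulated plant
communities.

## A worked example

```r
library(psfisim)

cfg <- sim_config()   # 100x100 grid, 12,000 steps, invasion at 10,001
sim <- run_simulation("Neg.Nest.20.NC", cfg, seed = 1, invasion = TRUE)
invader_percent_biomass(community_summary(sim, 12000))
#> [1] 99.15977
```

In a negative nested community (20 focal species hindering everyone,
negative conspecific feedback), the invader holds ~99% of community
biomass 2,000 steps after arriving — the resident community's average
growth rate is so depressed that the non-interacting invader overruns it.
Contrast the null control, where the invader usually goes extinct:

```r
plan <- build_full_plan(n_replicates = 5, base_seed = 1,
                        scenarios = c("Null", "Null.NC", "Neg.Nest.20.NC"),
                        invasion_arms = TRUE)
res <- run_plan(plan, cfg)
invasibility_ordering(res)[, c("scenario", "invader_pct_final_mean",
                               "rank", "dominant")]
#>         scenario invader_pct_final_mean rank dominant
#> 1 Neg.Nest.20.NC             99.2798414    1     TRUE
#> 2        Null.NC              1.6425744    2    FALSE
#> 3           Null              0.6069642    3    FALSE
```

`run_plan()` also returns `inv_simpson_pre`, `bray_curtis_change` and
`avg_growth_rate_pre` per replicate; `scenario_summary()` adds means with
95% confidence intervals over replicates.

A thin command-line front-end is installed as `exec/psfisim`
(`list-scenarios`, `simulate`, `summarise`) for batch use.

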