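#' Build the full factorial experiment plan
#'
#' Crosses the 38-scenario catalogue with the two invasion arms and
#' `n_replicates` replicates, in a stable order. Replicate `r` of every
#' (scenario, arm) cell uses seed `base_seed + r - 1`, so the same
#' replicate index faces the same stochastic stream in every cell and the
#' plan is reproducible from `base_seed` alone.
#'
#' @param n_replicates Replicates per scenario x arm cell.
#' @param base_seed Integer base seed.
#' @param scenarios Optional character vector of scenario names to restrict
#'   the plan to (default: all 38).
#' @param invasion_arms Logical vector of arms to include (default both).
#' @return An `experiment_plan` data frame with columns `scenario`,
#'   `invasion`, `replicate`, `seed`.
#' @examples
#' nrow(build_full_plan(100))  # 7600
#' @export
build_full_plan <- function(n_replicates = 100, base_seed = 1,
                            scenarios = psfi_scenarios()$name,
                            invasion_arms = c(FALSE, TRUE)) {
  stopifnot(n_replicates >= 1)
  plan <- expand.grid(replicate = seq_len(n_replicates),
                      invasion = invasion_arms, scenario = scenarios,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  plan <- plan[, c("scenario", "invasion", "replicate")]
  plan$seed <- base_seed + plan$replicate - 1L
  attr(plan, "base_seed") <- base_seed
  class(plan) <- c("experiment_plan", "data.frame")
  plan
}

metric_cols <- c("invader_pct_final", "inv_simpson_pre",
                 "bray_curtis_change", "avg_growth_rate_pre")

# recorded steps used for the pre-invasion and change-from summaries; at
# the study scale these resolve to exactly 10,000 and 5,000
summary_steps <- function(steps, config) {
  target_pre <- min(10000L, config$n_steps)
  if (!is.na(config$invasion_step))
    target_pre <- min(target_pre, config$invasion_step - 1L)
  pre <- max(steps[steps <= target_pre])
  before <- steps[steps <= min(5000L, pre)]
  cf <- if (length(before) && max(before) < pre) max(before)
        else min(steps)
  c(change_from = cf, pre = pre)
}

run_metrics <- function(sim, table) {
  ss <- summary_steps(sim$steps, sim$config)
  pre <- community_summary(sim, ss[["pre"]])
  from <- community_summary(sim, ss[["change_from"]])
  fin <- community_summary(sim, max(sim$steps))
  data.frame(
    pre_step = ss[["pre"]], change_from_step = ss[["change_from"]],
    final_step = max(sim$steps),
    invader_pct_final = invader_percent_biomass(fin),
    inv_simpson_pre = inverse_simpson(pre),
    bray_curtis_change = bray_curtis_change(from, pre),
    avg_growth_rate_pre = community_avg_growth_rate(pre, table))
}

#' Execute an experiment plan
#'
#' Runs every (scenario, invasion arm, replicate) of a plan and returns the
#' per-replicate metrics table: final invader biomass percentage,
#' pre-invasion inverse Simpson diversity, Bray-Curtis compositional change
#' between the two pre-invasion reference steps, and the resident
#' community's average growth rate. With `out_dir` set, each completed run
#' is cached as a one-row CSV and skipped on re-execution, making the batch
#' resumable.
#'
#' @param plan An [build_full_plan()] plan (any data frame with `scenario`,
#'   `invasion`, `replicate`, `seed` columns works).
#' @param config A [sim_config()] shared by all runs.
#' @param out_dir Optional cache/output directory.
#' @param verbose Print one line per run.
#' @return A data frame: plan columns plus `pre_step`, `change_from_step`,
#'   `final_step` and the four metric columns.
#' @export
run_plan <- function(plan, config = sim_config(), out_dir = NULL,
                     verbose = FALSE) {
  stopifnot(all(c("scenario", "invasion", "replicate", "seed") %in%
                  names(plan)))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  tables <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(plan))
  for (k in seq_len(nrow(plan))) {
    p <- plan[k, ]
    cache <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("%s__%s__r%03d.csv", p$scenario,
                                 if (p$invasion) "inv" else "noinv",
                                 p$replicate))
    if (!is.null(cache) && file.exists(cache)) {
      rows[[k]] <- read.csv(cache, stringsAsFactors = FALSE)
      next
    }
    if (!exists(p$scenario, envir = tables, inherits = FALSE))
      assign(p$scenario,
             build_interaction_table(p$scenario, config$n_resident_species),
             envir = tables)
    tab <- tables[[p$scenario]]
    sim <- run_simulation(p$scenario, config, seed = p$seed,
                          invasion = p$invasion, table = tab)
    row <- cbind(p, run_metrics(sim, tab), row.names = NULL)
    if (!is.null(cache)) write.csv(row, cache, row.names = FALSE)
    if (verbose)
      message(sprintf("%s %s r%d: invader %.2f%%", p$scenario,
                      if (p$invasion) "+inv" else "-inv", p$replicate,
                      row$invader_pct_final))
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

ci_half <- function(x) {
  n <- sum(!is.na(x))
  if (n < 2) return(NA_real_)
  qnorm(0.975) * sd(x, na.rm = TRUE) / sqrt(n)
}

#' Scenario-level summary of a metrics table
#'
#' Means with normal-approximation 95% confidence intervals
#' (mean +/- 1.96 SE over replicates) for every metric, by scenario and
#' invasion arm.
#'
#' @param results A [run_plan()] metrics table.
#' @return A data frame with one row per scenario x arm and, per metric,
#'   `<metric>_mean`, `<metric>_lo`, `<metric>_hi` columns, plus `n`.
#' @export
scenario_summary <- function(results) {
  stopifnot(all(metric_cols %in% names(results)))
  key <- interaction(results$scenario, results$invasion, drop = TRUE)
  parts <- lapply(split(results, key), function(d) {
    out <- data.frame(scenario = d$scenario[1], invasion = d$invasion[1],
                      n = nrow(d), stringsAsFactors = FALSE)
    for (m in metric_cols) {
      mu <- mean(d[[m]], na.rm = TRUE)
      h <- ci_half(d[[m]])
      out[[paste0(m, "_mean")]] <- mu
      out[[paste0(m, "_lo")]] <- mu - h
      out[[paste0(m, "_hi")]] <- mu + h
    }
    out
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$scenario, out$invasion), ]
}

#' Rank scenarios by invasibility
#'
#' Orders the with-invasion arms of a scenario summary by mean final
#' invader biomass percentage and flags scenarios where the invader became
#' dominant (mean > 10% of total biomass).
#'
#' @param summary A [scenario_summary()] table (or a [run_plan()] table,
#'   which is summarised first).
#' @param dominance_threshold Dominance cut-off in percent (default 10).
#' @return The summary rows with invasion, ordered by decreasing mean
#'   invader percentage, with `rank` and logical `dominant` columns.
#' @export
invasibility_ordering <- function(summary, dominance_threshold = 10) {
  if (!"invader_pct_final_mean" %in% names(summary))
    summary <- scenario_summary(summary)
  inv <- summary[summary$invasion, , drop = FALSE]
  inv <- inv[order(-inv$invader_pct_final_mean), ]
  inv$rank <- seq_len(nrow(inv))
  inv$dominant <- inv$invader_pct_final_mean > dominance_threshold
  rownames(inv) <- NULL
  inv
}
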