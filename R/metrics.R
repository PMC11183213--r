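#' Invader share of community biomass
#'
#' 100 x invader biomass / total community biomass — the invasibility
#' measure, taken at the final time step of an invaded run.
#'
#' @param summary A [community_summary()].
#' @return Percentage in \[0, 100\].
#' @export
invader_percent_biomass <- function(summary) {
  stopifnot(inherits(summary, "community_summary"))
  tot <- sum(summary$biomass)
  if (tot <= 0)
    stop("invader percentage is undefined for an empty community",
         call. = FALSE)
  100 * summary$biomass[[summary$n_resident + 1L]] / tot
}

resident_vector <- function(summary, basis = c("biomass", "abundance")) {
  basis <- match.arg(basis)
  summary[[basis]][seq_len(summary$n_resident)]
}

#' Inverse Simpson diversity (1/D)
#'
#' The reciprocal of the sum of squared relative shares. For a
#' `community_summary` the shares are taken over resident species only
#' (biomass by default), so pre-invasion diversity at step 10,000 excludes
#' the not-yet-present invader.
#'
#' @param x A numeric vector of non-negative abundances/biomasses, or a
#'   [community_summary()].
#' @param basis For summaries: `"biomass"` (default) or `"abundance"`.
#' @param ... Passed to methods.
#' @return 1/D, in \[1, number of species with non-zero share\].
#' @examples
#' inverse_simpson(c(1, 1, 1, 1))  # 4: perfectly even
#' @export
inverse_simpson <- function(x, ...) UseMethod("inverse_simpson")

#' @rdname inverse_simpson
#' @export
inverse_simpson.default <- function(x, ...) {
  stopifnot(is.numeric(x), all(x >= 0))
  tot <- sum(x)
  if (tot <= 0)
    stop("inverse Simpson diversity is undefined for an empty community",
         call. = FALSE)
  p <- x / tot
  1 / sum(p^2)
}

#' @rdname inverse_simpson
#' @export
inverse_simpson.community_summary <- function(x, basis = "biomass", ...) {
  inverse_simpson(resident_vector(x, basis))
}

#' Bray-Curtis compositional change
#'
#' Bray-Curtis distance `sum(|x - y|) / sum(x + y)` between two community
#' vectors. For summaries, computed on resident species biomass — the
#' compositional change between two pre-invasion time points (steps 5,000
#' and 10,000 in the study design).
#'
#' @param x,y Non-negative numeric vectors of equal length, or two
#'   [community_summary()] objects from the same replicate.
#' @param basis For summaries: `"biomass"` (default) or `"abundance"`.
#' @param ... Passed to methods.
#' @return A distance in \[0, 1\]; 0 iff identical, 1 for disjoint species
#'   sets.
#' @examples
#' bray_curtis_change(c(6, 2), c(2, 6))  # 0.5
#' @export
bray_curtis_change <- function(x, y, ...) UseMethod("bray_curtis_change")

#' @rdname bray_curtis_change
#' @export
bray_curtis_change.default <- function(x, y, ...) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            all(x >= 0), all(y >= 0))
  denom <- sum(x + y)
  if (denom <= 0)
    stop("Bray-Curtis distance is undefined for two empty communities",
         call. = FALSE)
  sum(abs(x - y)) / denom
}

#' @rdname bray_curtis_change
#' @export
bray_curtis_change.community_summary <- function(x, y, basis = "biomass",
                                                 ...) {
  stopifnot(inherits(y, "community_summary"),
            x$n_resident == y$n_resident)
  bray_curtis_change(resident_vector(x, basis), resident_vector(y, basis))
}

#' Average growth rate of the resident community
#'
#' The expected establishment growth rate of a random resident recruit
#' landing on a cell conditioned by a random resident — the double sum
#' `sum_i sum_j p_i p_j rate(i, j)` over resident relative frequencies
#' `p` (individual counts by default). Under global dispersal this is the
#' rate a random propagule experiences, and serves as the productivity
#' measure of the pre-invasion community. Bounded by the slow and fast
#' rate classes.
#'
#' @param x A numeric frequency/abundance vector over resident species, or
#'   a [community_summary()].
#' @param table The scenario's `interaction_table`.
#' @param basis For summaries: `"abundance"` (default) or `"biomass"`.
#' @param ... Passed to methods.
#' @return The expected per-step growth rate.
#' @examples
#' tab <- apply_conspecific(build_null(3))
#' community_avg_growth_rate(c(1, 0, 0), tab)  # monoculture: slow rate
#' @export
community_avg_growth_rate <- function(x, table, ...)
  UseMethod("community_avg_growth_rate")

#' @rdname community_avg_growth_rate
#' @export
community_avg_growth_rate.default <- function(x, table, ...) {
  stopifnot(inherits(table, "interaction_table"),
            is.numeric(x), all(x >= 0),
            length(x) == table$n_resident)
  tot <- sum(x)
  if (tot <= 0)
    stop("average growth rate is undefined for an empty community",
         call. = FALSE)
  p <- x / tot
  res <- seq_len(table$n_resident)
  drop(p %*% table$rates[res, res] %*% p)
}

#' @rdname community_avg_growth_rate
#' @export
community_avg_growth_rate.community_summary <- function(x, table,
                                                        basis = "abundance",
                                                        ...) {
  community_avg_growth_rate(resident_vector(x, basis), table)
}
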