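# Blank table: every (recruit, soil) pair at the standard rate, with the
# invader's fixed entries (fast on its own soil, no heterospecific effects).
new_interaction_table <- function(n_resident = 100, classes = growth_rates()) {
  stopifnot(n_resident >= 1)
  s <- n_resident + 1L  # invader index
  rates <- matrix(classes[["standard"]], nrow = s, ncol = s)
  rates[s, s] <- classes[["fast"]]
  structure(
    list(rates = rates, n_resident = as.integer(n_resident),
         invader = s, classes = classes),
    class = "interaction_table")
}

stop_if_bad_group <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)

hetero_value <- function(sign, classes) {
  sign <- match.arg(sign, c("positive", "negative"))
  if (sign == "positive") classes[["fast"]] else classes[["slow"]]
}

#' Build a PSFI interaction table
#'
#' An interaction table maps every ordered pair (recruit species, soil
#' conditioning species) to a per-step growth rate; it encodes the
#' plant-soil feedback network of a scenario. Rows are recruit species,
#' columns are soil-conditioning species; the invader occupies the last
#' index. `rate(i, j)` non-standard means soil conditioned by species j
#' changes the establishment growth of species i. Unconditioned soil always
#' gives the standard rate.
#'
#' * `build_modular()`: species are partitioned into contiguous modules of
#'   `group_size`; every heterospecific pair within a module affects each
#'   other bidirectionally, with no cross-module effects.
#' * `build_nested()`: the first `group_size` species (the focal set)
#'   one-directionally affect every other species, including each other;
#'   non-focal species affect nobody.
#' * `build_ring()`: species sit on a circle and each species affects the
#'   next `group_size` species clockwise, forming an intransitive ring.
#' * `build_null()`: no heterospecific interactions.
#' * `apply_conspecific()`: set every resident's conspecific entry
#'   `rate(i, i)` to slow (the invader's positive conspecific entry is
#'   untouched). Idempotent.
#' * `build_interaction_table()`: dispatch on a [psfi_scenario()].
#'
#' @param n_species,n_resident Number of resident species (default 100).
#' @param group_size Module size, focal-set size, or ring out-degree.
#' @param sign `"positive"` (affected species grow fast on that soil) or
#'   `"negative"` (slow).
#' @param classes Growth-rate classes from [growth_rates()].
#' @param table An `interaction_table`.
#' @param scenario A `psfi_scenario` or a scenario name string.
#' @return An `interaction_table`: a list with elements `rates` (numeric
#'   matrix over residents plus invader), `n_resident`, `invader` (index),
#'   `classes`.
#' @examples
#' tab <- build_modular(100, 5, "negative")
#' interaction_rate(tab, 1, 2)  # slow: same module
#' interaction_rate(tab, 1, 6)  # standard: different module
#' @rdname build_interaction_table
#' @export
build_modular <- function(n_species = 100, group_size, sign,
                          classes = growth_rates()) {
  stop_if_bad_group(n_species %% group_size == 0,
                    "group_size must divide n_species in a modular network")
  tab <- new_interaction_table(n_species, classes)
  v <- hetero_value(sign, classes)
  for (m in seq_len(n_species %/% group_size)) {
    idx <- ((m - 1L) * group_size + 1L):(m * group_size)
    tab$rates[idx, idx] <- v
    for (i in idx) tab$rates[i, i] <- classes[["standard"]]
  }
  tab
}

#' @rdname build_interaction_table
#' @export
build_nested <- function(n_species = 100, group_size, sign,
                         classes = growth_rates()) {
  stop_if_bad_group(group_size < n_species,
                    "group_size must be smaller than n_species in a nested network")
  tab <- new_interaction_table(n_species, classes)
  v <- hetero_value(sign, classes)
  focal <- seq_len(group_size)
  tab$rates[seq_len(n_species), focal] <- v
  for (j in focal) tab$rates[j, j] <- classes[["standard"]]
  tab
}

#' @rdname build_interaction_table
#' @export
build_ring <- function(n_species = 100, group_size, sign,
                       classes = growth_rates()) {
  stop_if_bad_group(group_size < n_species,
                    "group_size must be smaller than n_species in a ring network")
  tab <- new_interaction_table(n_species, classes)
  v <- hetero_value(sign, classes)
  for (j in seq_len(n_species)) {
    targets <- ((j - 1L + seq_len(group_size)) %% n_species) + 1L
    tab$rates[targets, j] <- v
  }
  tab
}

#' @rdname build_interaction_table
#' @export
build_null <- function(n_species = 100, classes = growth_rates()) {
  new_interaction_table(n_species, classes)
}

#' @rdname build_interaction_table
#' @export
apply_conspecific <- function(table) {
  stopifnot(inherits(table, "interaction_table"))
  for (i in seq_len(table$n_resident))
    table$rates[i, i] <- table$classes[["slow"]]
  table
}

#' @rdname build_interaction_table
#' @export
build_interaction_table <- function(scenario, n_resident = 100,
                                    classes = growth_rates()) {
  if (is.character(scenario)) scenario <- parse_scenario(scenario)
  stopifnot(inherits(scenario, "psfi_scenario"))
  tab <- switch(scenario$architecture,
    null = build_null(n_resident, classes),
    modular = build_modular(n_resident, scenario$group_size, scenario$sign,
                            classes),
    nested = build_nested(n_resident, scenario$group_size, scenario$sign,
                          classes),
    ring = build_ring(n_resident, scenario$group_size, scenario$sign,
                      classes))
  if (scenario$conspecific_negative) tab <- apply_conspecific(tab)
  tab
}

#' Look up an establishment growth rate
#'
#' The rate a recruit of `recruit` establishes with on soil last conditioned
#' by `soil` (`0` = unconditioned, always standard). This rate is fixed for
#' the plant's lifetime.
#'
#' @param table An `interaction_table`.
#' @param recruit Species index of the recruit (invader = `table$invader`).
#' @param soil Species index of the conditioning species, or 0.
#' @return The numeric per-step growth rate.
#' @export
interaction_rate <- function(table, recruit, soil) {
  stopifnot(inherits(table, "interaction_table"))
  s <- table$invader
  if (!all(recruit >= 1 & recruit <= s))
    stop("unknown recruit species index", call. = FALSE)
  if (!all(soil >= 0 & soil <= s))
    stop("unknown soil species index", call. = FALSE)
  ifelse(soil == 0, table$classes[["standard"]],
         table$rates[cbind(recruit, pmax(soil, 1))])
}

# label each numeric rate with its class name (slow/standard/fast)
rate_label <- function(values, classes) {
  names(classes)[match(values, classes)]
}

#' @export
print.interaction_table <- function(x, ...) {
  ns <- sum(x$rates[seq_len(x$n_resident), seq_len(x$n_resident)] !=
              x$classes[["standard"]])
  cat("<interaction_table> ", x$n_resident, " resident species + invader; ",
      ns, " non-standard resident entries\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.interaction_table <- function(x, ...) {
  s <- x$invader
  data.frame(
    recruit_species = rep(seq_len(s), times = s),
    soil_species = rep(seq_len(s), each = s),
    rate_class = rate_label(as.vector(x$rates), x$classes),
    rate = as.vector(x$rates))
}

#' Export an interaction table
#'
#' Writes either the long three-column form (recruit species, soil species,
#' rate class) or the dense rate matrix as CSV, for inspection and
#' cross-language checks.
#'
#' @param table An `interaction_table`.
#' @param path Output file path.
#' @param format `"long"` or `"matrix"`.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(table, path,
                                    format = c("long", "matrix")) {
  format <- match.arg(format)
  if (format == "long") {
    write.csv(as.data.frame(table), path, row.names = FALSE)
  } else {
    m <- table$rates
    dimnames(m) <- list(recruit = seq_len(nrow(m)), soil = seq_len(ncol(m)))
    write.csv(m, path)
  }
  invisible(path)
}

#' Export the scenario catalogue
#'
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scenario_catalogue <- function(path) {
  write.csv(psfi_scenarios(), path, row.names = FALSE)
  invisible(path)
}
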