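#' Growth-rate classes
#'
#' The three per-step multiplicative growth rates a plant can establish
#' with, depending on the soil conditioning of its cell: `slow` (negative
#' feedback), `standard` (no feedback, including unconditioned soil) and
#' `fast` (positive feedback).
#'
#' @param slow,standard,fast Multiplicative growth factors per time step.
#'   Must satisfy `slow < standard < fast`.
#' @return A named numeric vector with elements `slow`, `standard`, `fast`.
#' @examples
#' growth_rates()
#' @export
growth_rates <- function(slow = 1.49, standard = 1.65, fast = 1.82) {
  if (!(slow < standard && standard < fast))
    stop("growth rates must satisfy slow < standard < fast", call. = FALSE)
  c(slow = slow, standard = standard, fast = fast)
}

.architectures <- c("null", "modular", "nested", "ring")
.arch_token <- c(modular = "Mod", nested = "Nest", ring = "Ring")
.sign_token <- c(positive = "Pos", negative = "Neg")

#' Create a PSFI scenario specification
#'
#' A scenario fixes the heterospecific interaction architecture (`null`,
#' `modular`, `nested` or `ring`), the sign of heterospecific effects, the
#' group size controlling network connectivity, whether residents suffer
#' negative conspecific feedback, and whether an invasion event occurs.
#'
#' @param architecture One of `"null"`, `"modular"`, `"nested"`, `"ring"`.
#' @param sign `"positive"`, `"negative"`, or `"none"` (required and only
#'   allowed for the null architecture).
#' @param group_size Species per module (modular), number of focal species
#'   (nested) or out-degree per species (ring). Absent (`NA`) for null.
#' @param conspecific_negative Logical; if `TRUE` residents grow at the slow
#'   rate on soil conditioned by a conspecific.
#' @param invasion Logical; whether an invader is introduced.
#' @return An object of class `psfi_scenario`.
#' @seealso [parse_scenario()], [psfi_scenarios()]
#' @examples
#' psfi_scenario("nested", "negative", 20, conspecific_negative = TRUE)
#' @export
psfi_scenario <- function(architecture, sign = "none", group_size = NA,
                          conspecific_negative = FALSE, invasion = FALSE) {
  architecture <- match.arg(architecture, .architectures)
  sign <- match.arg(sign, c("none", "positive", "negative"))
  if (architecture == "null") {
    if (sign != "none")
      stop("the null architecture has no heterospecific sign", call. = FALSE)
    if (!is.na(group_size))
      stop("the null architecture has no group size", call. = FALSE)
  } else {
    if (sign == "none")
      stop("architecture '", architecture, "' requires a positive or ",
           "negative heterospecific sign", call. = FALSE)
    if (is.na(group_size) || group_size < 1)
      stop("architecture '", architecture, "' requires a positive group ",
           "size", call. = FALSE)
    group_size <- as.integer(group_size)
  }
  structure(
    list(architecture = architecture, sign = sign,
         group_size = if (architecture == "null") NA_integer_ else group_size,
         conspecific_negative = isTRUE(conspecific_negative),
         invasion = isTRUE(invasion)),
    class = "psfi_scenario")
}

#' Canonical scenario name
#'
#' Formats a scenario as its catalogue name, e.g. `"Neg.Nest.20.NC"` or
#' `"Null"`. The `NC` suffix marks negative conspecific feedback; the
#' invasion toggle is not part of the name (it is an experiment arm).
#'
#' @param scenario A `psfi_scenario`.
#' @return A character scalar.
#' @export
scenario_name <- function(scenario) {
  stopifnot(inherits(scenario, "psfi_scenario"))
  base <- if (scenario$architecture == "null") "Null"
  else paste(.sign_token[[scenario$sign]],
             .arch_token[[scenario$architecture]],
             scenario$group_size, sep = ".")
  if (scenario$conspecific_negative) paste0(base, ".NC") else base
}

#' Parse a scenario name
#'
#' Inverse of [scenario_name()]: `"Pos.Mod.10"` becomes a modular, positive,
#' group-size-10 scenario without negative conspecific feedback.
#'
#' @param name A scenario name such as `"Null.NC"` or `"Neg.Ring.5"`.
#' @param invasion Logical; invasion toggle to attach to the parsed spec.
#' @return A `psfi_scenario`.
#' @export
parse_scenario <- function(name, invasion = FALSE) {
  stopifnot(is.character(name), length(name) == 1)
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  nc <- length(parts) > 0 && parts[length(parts)] == "NC"
  if (nc) parts <- parts[-length(parts)]
  if (identical(parts, "Null"))
    return(psfi_scenario("null", conspecific_negative = nc,
                         invasion = invasion))
  if (length(parts) != 3)
    stop("cannot parse scenario name '", name, "'", call. = FALSE)
  sign <- names(.sign_token)[match(parts[1], .sign_token)]
  arch <- names(.arch_token)[match(parts[2], .arch_token)]
  g <- suppressWarnings(as.integer(parts[3]))
  if (is.na(sign) || is.na(arch) || is.na(g))
    stop("cannot parse scenario name '", name, "'", call. = FALSE)
  psfi_scenario(arch, sign, g, conspecific_negative = nc,
                invasion = invasion)
}

#' @export
print.psfi_scenario <- function(x, ...) {
  cat("<psfi_scenario> ", scenario_name(x),
      if (x$invasion) " (+invasion)" else "", "\n", sep = "")
  invisible(x)
}

#' Enumerate the PSFI scenario catalogue
#'
#' All 38 scenarios of the study design in a stable order: the null control
#' and each (sign x architecture x group size) combination over group sizes
#' 5, 10 and 20 — 19 heterospecific scenarios — each paired with and without
#' negative conspecific feedback. Crossing with the invasion arm is done by
#' the experiment layer ([build_full_plan()]).
#'
#' @return A data frame with columns `name`, `architecture`, `sign`,
#'   `group_size`, `conspecific_negative`.
#' @examples
#' nrow(psfi_scenarios())  # 38
#' @export
psfi_scenarios <- function() {
  base <- list(psfi_scenario("null"))
  for (arch in c("modular", "ring", "nested"))
    for (sign in c("positive", "negative"))
      for (g in c(5L, 10L, 20L))
        base[[length(base) + 1L]] <- psfi_scenario(arch, sign, g)
  rows <- list()
  for (sc in base) {
    for (nc in c(FALSE, TRUE)) {
      sc$conspecific_negative <- nc
      rows[[length(rows) + 1L]] <- data.frame(
        name = scenario_name(sc), architecture = sc$architecture,
        sign = sc$sign, group_size = sc$group_size,
        conspecific_negative = nc, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
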