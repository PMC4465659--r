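#' Compact nearest-neighbour RNA energy model
#'
#' A deliberately small thermodynamic model for MFE folding: stacking
#' enthalpies/entropies for the six admissible pairs (Watson-Crick plus GU
#' wobble), logarithmic loop penalties stored as pure entropies, and an
#' affine multiloop cost. Every free energy is derived uniformly as
#' \deqn{\Delta G(T) = \Delta H - (T + 273.15)\,\Delta S / 1000}
#' (\eqn{\Delta H} kcal/mol, \eqn{\Delta S} cal/mol/K), so the whole model
#' responds smoothly to the temperature option. It is *not* the Turner
#' parameter set: correctness of the folder is defined by exact agreement
#' with exhaustive enumeration under this same model, not by matching any
#' external program's structures.
#'
#' Pair type codes used throughout: 1 AU, 2 UA, 3 GC, 4 CG, 5 GU, 6 UG.
#'
#' @param temperature Folding temperature in degrees Celsius. The default
#'   3.5 is the approximate ambient temperature of the cold stenothermal
#'   fish the method was designed around.
#' @param max_loop Largest number of unpaired bases in a bulge/internal
#'   loop (default 30).
#' @param min_hairpin Minimum unpaired bases closing a hairpin (fixed 3).
#' @return An object of class `energy_model`: the raw `dH`/`dS` tables and
#'   the `dG` values precomputed at `temperature`.
#' @export
energy_model <- function(temperature = 3.5, max_loop = 30L, min_hairpin = 3L) {
  # per-pair stacking strength (kcal/mol): GC strongest, GU weakest
  strength <- c(AU = 2.8, UA = 2.8, GC = 5.0, CG = 5.0, GU = 1.6, UG = 1.6)
  # stack of outer pair p over inner pair q: cooperative bonus of 2.4 kcal/mol
  dH_stack <- -outer(strength, strength, `+`) - 2.4
  dS_stack <- 2.7 * dH_stack  # cal/mol/K; GC/GC stack ~ -2.0 kcal/mol at 37 C

  max_len <- 1200L
  l <- seq_len(max_len)
  dS_hairpin <- -(16 + 5 * log(pmax(l, min_hairpin) / min_hairpin))
  dS_bulge <- -(13 + 5 * log(l))
  dS_internal <- -(6 + 5 * log(pmax(l, 2) / 2))
  # multiloop: a (closing) + b per branch + c per unpaired base, as entropies
  dS_multi <- c(a = -12, b = -1.5, c = -0.4)

  m <- structure(
    list(
      temperature = temperature,
      min_hairpin = as.integer(min_hairpin),
      max_loop = as.integer(max_loop),
      dH_stack = dH_stack, dS_stack = dS_stack,
      dS_hairpin = dS_hairpin, dS_bulge = dS_bulge,
      dS_internal = dS_internal, dS_multi = dS_multi
    ),
    class = "energy_model"
  )
  model_at_temperature(m, temperature)
}

#' Re-derive a model's free energies at another temperature
#'
#' @param base_model An [energy_model()].
#' @param temperature New temperature in degrees Celsius (sanity range
#'   -10..100).
#' @return The model with all `dG` entries recomputed.
#' @export
model_at_temperature <- function(base_model, temperature) {
  stopifnot(inherits(base_model, "energy_model"))
  if (temperature < -10 || temperature > 100) {
    stop("temperature outside the physically sensible range -10..100 C")
  }
  tk <- temperature + 273.15
  dg <- function(dh, ds) dh - tk * ds / 1000
  base_model$temperature <- temperature
  base_model$dG_stack <- dg(base_model$dH_stack, base_model$dS_stack)
  base_model$dG_hairpin <- dg(0, base_model$dS_hairpin)
  base_model$dG_bulge <- dg(0, base_model$dS_bulge)
  base_model$dG_internal <- dg(0, base_model$dS_internal)
  base_model$dG_multi <- dg(0, base_model$dS_multi)
  stopifnot(all(base_model$dG_hairpin >= 0), all(base_model$dG_bulge >= 0),
            all(base_model$dG_internal >= 0), all(base_model$dG_multi >= 0))
  base_model
}

#' Temperature grid of energy models
#'
#' @param t_min,t_max,t_step Grid in degrees Celsius, both ends inclusive;
#'   the defaults (1 to 4 by 0.1) give 31 models.
#' @param base_model Model to re-derive (default [energy_model()]).
#' @return List of [energy_model()]s, named by temperature.
#' @export
temperature_grid <- function(t_min = 1.0, t_max = 4.0, t_step = 0.1,
                             base_model = energy_model()) {
  if (t_step <= 0) stop("`t_step` must be positive")
  if (t_max < t_min) stop("`t_max` must be >= `t_min`")
  n <- round((t_max - t_min) / t_step) + 1L
  temps <- t_min + (seq_len(n) - 1L) * t_step
  stats::setNames(lapply(temps, model_at_temperature, base_model = base_model),
                  formatC(temps, format = "f", digits = 1))
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> T =", x$temperature, "C, min hairpin", x$min_hairpin,
      ", max loop", x$max_loop, "\n")
  cat("  stack dG range:", round(min(x$dG_stack), 2), "..",
      round(max(x$dG_stack), 2), "kcal/mol\n")
  invisible(x)
}
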