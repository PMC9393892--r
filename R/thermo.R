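# Relative energies, the energy-window selection, and Boltzmann populations.

energy_column <- function(ensemble, energy_field) {
  energy_field <- match.arg(energy_field, c("electronic", "enthalpy", "gibbs"))
  e <- ensemble[[energy_field]]
  if (is.null(e) || any(!is.finite(e)))
    stop("energy unavailable: field '", energy_field,
         "' missing for at least one conformer", call. = FALSE)
  e
}

#' Relative conformer energies in kcal/mol
#'
#' Energies of the selected field relative to the most stable conformer,
#' converted from Hartree with 1 Hartree = 627.509474 kcal/mol. The minimum
#' entry is exactly zero.
#'
#' @param ensemble A `vcd_ensemble`.
#' @param energy_field One of `"electronic"`, `"enthalpy"`, `"gibbs"`.
#' @return Tibble with columns `label`, `delta_e` (kcal/mol).
#' @export
relative_energies <- function(ensemble, energy_field = "electronic") {
  e <- energy_column(ensemble, energy_field)
  tibble::tibble(label = ensemble$label,
                 delta_e = (e - min(e)) * .const$hartree_kcal)
}

#' Keep conformers within an energy window of the minimum
#'
#' Retains conformers whose relative energy is at most `window` kcal/mol
#' above the most stable conformer (inclusive comparison, reading "at most"
#' inclusively). The minimum-energy conformer is always kept, so the result
#' is never empty; input order is preserved. The default window of
#' 2.5 kcal/mol is the threshold commonly used to select which conformers
#' proceed to geometry optimization and spectral calculation.
#'
#' @inheritParams relative_energies
#' @param window Window width in kcal/mol; must be positive.
#' @return The filtered `vcd_ensemble`.
#' @export
energy_window_filter <- function(ensemble, window = 2.5,
                                 energy_field = "electronic") {
  stopifnot(window > 0)
  de <- relative_energies(ensemble, energy_field)$delta_e
  out <- ensemble[de <= window, ]
  class(out) <- unique(c("vcd_ensemble", class(out)))
  out
}

#' Boltzmann populations of an ensemble
#'
#' Fractional population of each conformer at temperature `T`:
#' `w_i = exp(-dE_i / RT) / sum_j exp(-dE_j / RT)` with relative energies in
#' kcal/mol and `R = 1.987204e-3` kcal/(mol K). Computed from energies
#' shifted to the minimum, so very large energy gaps cannot underflow the
#' numerator of the most stable conformer. Gibbs free energies are the
#' conventional choice for spectral averaging; enthalpy or electronic energy
#' can be selected to study the sensitivity of the averaged spectrum to the
#' weighting scheme.
#'
#' @inheritParams relative_energies
#' @param energy_field Energy field to weight on (default `"gibbs"`).
#' @param temperature Temperature in K (default 298.15).
#' @return A `vcd_weights` tibble with columns `label`, `delta_e` (kcal/mol),
#'   `weight`; attributes `energy_field` and `temperature`.
#' @export
boltzmann_weights <- function(ensemble, energy_field = "gibbs",
                              temperature = 298.15) {
  stopifnot(temperature > 0)
  rel <- relative_energies(ensemble, energy_field)
  q <- exp(-rel$delta_e / (.const$gas_constant_kcal * temperature))
  out <- tibble::tibble(label = rel$label, delta_e = rel$delta_e,
                        weight = q / sum(q))
  attr(out, "energy_field") <- energy_field
  attr(out, "temperature") <- temperature
  class(out) <- c("vcd_weights", class(out))
  out
}

#' Conformers with significant Boltzmann weight
#'
#' Labels whose weight is strictly greater than `cutoff` (default 5%),
#' ordered by descending weight. Commonly used to report how many conformers
#' matter for the averaged spectrum; by default it is bookkeeping only and
#' does not truncate the average.
#'
#' @param weights A `vcd_weights` tibble from [boltzmann_weights()].
#' @param cutoff Weight threshold (fraction); strict comparison.
#' @return Character vector of labels (possibly empty).
#' @export
significant_conformers <- function(weights, cutoff = 0.05) {
  sel <- weights[weights$weight > cutoff, ]
  sel$label[order(sel$weight, decreasing = TRUE)]
}
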