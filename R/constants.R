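# Physical constants used throughout. Units follow the conventions of the
# quantum-chemistry outputs this package consumes: coordinates in Angstrom,
# energies in Hartree, user-facing thresholds in kcal/mol, frequencies in cm^-1.

#' Physical constants
#'
#' @description
#' Named constants used by the package:
#' \describe{
#'   \item{hartree_kcal}{1 Hartree in kcal/mol (627.509474).}
#'   \item{gas_constant_kcal}{Gas constant R in kcal/(mol K)
#'     (1.987204e-3).}
#'   \item{rotconst_amuA2}{Numerator of B = h / (8 pi^2 c I): rotational
#'     constant in cm^-1 when the moment of inertia I is in amu Angstrom^2
#'     (16.8576304).}
#'   \item{ir_epsilon, vcd_epsilon}{Conversion factors from dipole strength
#'     (10^-40 esu^2 cm^2) and rotational strength (10^-44 esu^2 cm^2) to
#'     molar absorptivity; they cancel in all normalized overlap values and
#'     matter only for absolute intensity axes.}
#' }
#' @keywords internal
#' @name vcd_constants
NULL

.const <- list(
  hartree_kcal      = 627.509474,
  gas_constant_kcal = 1.987204e-3,
  rotconst_amuA2    = 16.8576304,
  # epsilon(nu) = nu * sum_i D_i L_i(nu) / 2.296e-39 with D in esu^2 cm^2;
  # table values carry 1e-40 (IR) and 1e-44 (VCD, with an extra factor 4).
  ir_epsilon        = 1e-40 / 2.296e-39,
  vcd_epsilon       = 4e-44 / 2.296e-39
)

#' Most-abundant-isotope atomic masses (amu)
#'
#' Masses of the most abundant isotope for the elements commonly found in
#' organic and bioorganic molecules. Used for moments of inertia and optional
#' mass-weighted superposition. Deuterium is available as "D".
#'
#' @return Named numeric vector of masses in amu.
#' @examples
#' atomic_masses()[c("H", "C", "N", "O")]
#' @export
atomic_masses <- function() {
  c(
    H  = 1.00782503, D  = 2.01410178, He = 4.00260325,
    Li = 7.01600344, Be = 9.01218306, B  = 11.00930536,
    C  = 12.0,       N  = 14.00307401, O = 15.99491462,
    F  = 18.99840316, Ne = 19.99244018,
    Na = 22.98976928, Mg = 23.98504170, Al = 26.98153853,
    Si = 27.97692653, P  = 30.97376200, S  = 31.97207117,
    Cl = 34.96885268, Ar = 39.96238312,
    K  = 38.96370649, Ca = 39.96259086, Sc = 44.95590829,
    Ti = 47.94794198, V  = 50.94395704, Cr = 51.94050623,
    Mn = 54.93804391, Fe = 55.93493633, Co = 58.93319429,
    Ni = 57.93534241, Cu = 62.92959772, Zn = 63.92914201,
    Ga = 68.92557353, Ge = 73.92117776, As = 74.92159457,
    Se = 79.91652176, Br = 78.91833760, Kr = 83.91149773,
    I  = 126.90447190
  )
}

element_mass <- function(symbols) {
  m <- atomic_masses()[symbols]
  if (anyNA(m)) {
    bad <- unique(symbols[is.na(m)])
    stop("no atomic mass available for element(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(m)
}

is_valid_element <- function(symbols) {
  symbols %in% names(atomic_masses())
}
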