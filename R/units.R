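#' Unit system constants
#'
#' The package works throughout in "metal-like" units: energies in eV,
#' lengths in Angstrom, charges in units of the elementary charge e, masses
#' in amu and time in fs. Because 1 amu A^2/fs^2 is not 1 eV, kinetic-energy
#' and force/mass conversions carry an explicit factor (`mv2_to_eV` and its
#' inverse `acc_factor`); all exported energies, temperatures and forces are
#' already converted.
#'
#' @return A list of named constants:
#' \describe{
#'   \item{coulomb}{Coulomb constant, 14.399645 eV A / e^2.}
#'   \item{kB}{Boltzmann constant, 8.617333e-5 eV / K.}
#'   \item{hartree}{1 Hartree in eV (27.211386); used only when reporting
#'     energy drifts in atomic units.}
#'   \item{mv2_to_eV}{Conversion from amu (A/fs)^2 to eV (103.642697...).}
#'   \item{acc_factor}{Conversion in a = F/m from (eV/A)/amu to A/fs^2,
#'     the reciprocal of `mv2_to_eV`.}
#' }
#' @examples
#' u <- units_shellmd()
#' # thermal kinetic energy of one particle at 300 K, in eV:
#' 1.5 * u$kB * 300
#' @export
units_shellmd <- function() {
  mv2 <- 103.6426965
  list(
    coulomb = 14.399645,
    kB = 8.617333e-5,
    hartree = 27.211386,
    mv2_to_eV = mv2,
    acc_factor = 1 / mv2
  )
}

# internal shorthands (constants, not user-facing)
.C_COUL <- 14.399645
.KB <- 8.617333e-5
.HARTREE <- 27.211386
.MV2E <- 103.6426965
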