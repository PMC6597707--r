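#' Physical constants and unit conversion factors
#'
#' Internal unit convention: dynamics are carried out in angstrom / femtosecond
#' / atomic mass unit / elementary charge; energies are reported in eV,
#' momenta in atomic units (a.u.), distances in angstrom and times in fs.
#' `unit_system()` collects every conversion factor the package uses so that
#' all stages share one set of constants.
#'
#' @return A list with components:
#'   \describe{
#'     \item{hartree_to_eV}{27.211386...}
#'     \item{bohr_to_angstrom}{0.529177...}
#'     \item{amu_to_au_mass}{electron masses per amu, 1822.888...}
#'     \item{coulomb_constant_eV_angstrom}{e^2/(4 pi eps0) in eV * angstrom,
#'       14.3996...}
#'     \item{amu_angfs2_to_eV}{kinetic-energy factor: 1 amu * (angstrom/fs)^2
#'       in eV}
#'     \item{amu_angfs_to_au_momentum}{1 amu * angstrom/fs in a.u. of momentum}
#'     \item{au_momentum_si}{1 a.u. of momentum in kg m/s}
#'     \item{amu_kg}{1 amu in kg}
#'     \item{elementary_charge_C}{e in coulomb}
#'   }
#' @export
unit_system <- function() {
  amu_kg <- 1.66053906660e-27
  e_C    <- 1.602176634e-19
  hbar   <- 1.054571817e-34
  bohr_m <- 0.529177210903e-10
  p_au   <- hbar / bohr_m                      # a.u. momentum in kg m/s
  list(
    hartree_to_eV                = 27.211386245988,
    bohr_to_angstrom             = 0.529177210903,
    amu_to_au_mass               = 1822.888486209,
    coulomb_constant_eV_angstrom = 14.3996454785,
    amu_angfs2_to_eV             = amu_kg * 1e10 / e_C,   # ~103.64
    amu_angfs_to_au_momentum     = amu_kg * 1e5 / p_au,   # ~83.32
    au_momentum_si               = p_au,
    amu_kg                       = amu_kg,
    elementary_charge_C          = e_C
  )
}

#' Angstrom / bohr round-trip conversions
#'
#' @param x numeric vector of lengths.
#' @return converted lengths.
#' @export
angstrom_to_bohr <- function(x) x / unit_system()$bohr_to_angstrom

#' @rdname angstrom_to_bohr
#' @export
bohr_to_angstrom <- function(x) x * unit_system()$bohr_to_angstrom
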