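#' Physical constants and unit conversions
#'
#' The package works in a fixed internal unit system: lengths in angstrom
#' (\eqn{\mathrm{\AA}}), times in femtoseconds, masses in atomic mass units
#' (amu) and energies in electronvolts.  Angular momentum is reported in
#' atomic units, 1 au = \eqn{\hbar}.  These helpers convert between the
#' mechanical unit (amu A^2/fs, amu A^2/fs^2) and the reporting units
#' (au, eV).
#'
#' @format NULL
#' @name chirodyn-units
#' @keywords internal
NULL

# CODATA 2018 values
.kB_eV <- 8.617333262e-5           # Boltzmann constant, eV / K
.amu_kg <- 1.66053906660e-27       # atomic mass unit, kg
.eV_J <- 1.602176634e-19           # electronvolt, J
.hbar_Js <- 1.054571817e-34        # reduced Planck constant, J s

# 1 amu A^2 / fs^2 expressed in eV (kinetic-energy conversion)
.eV_per_amuA2fs2 <- .amu_kg * 1e10 / .eV_J   # 103.6427

# acceleration conversion: force [eV/A] / mass [amu] -> [A/fs^2]
.acc_conv <- 1 / .eV_per_amuA2fs2            # 9.648533e-3

# 1 amu A^2 / fs expressed in units of hbar (angular momentum)
.au_per_amuA2fs <- .amu_kg * 1e-20 / 1e-15 / .hbar_Js   # 157.4611

# 1 A / fs expressed in m/s
.ms_per_Afs <- 1e5

#' Convert angular momentum from mechanical units to au (hbar)
#'
#' @param L angular momentum in amu A^2/fs.
#' @return angular momentum in atomic units (multiples of \eqn{\hbar}).
#' @examples
#' amuA2fs_to_au(2)  # 314.92 au
#' @export
amuA2fs_to_au <- function(L) L * .au_per_amuA2fs

#' @rdname amuA2fs_to_au
#' @export
au_to_amuA2fs <- function(L) L / .au_per_amuA2fs

#' Thermal energy k_B T in eV
#'
#' @param temperature temperature in kelvin.
#' @return \eqn{k_B T} in eV (0.025852 eV at 300 K).
#' @export
kBT_eV <- function(temperature) .kB_eV * temperature
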