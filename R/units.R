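#' Physical constants and unit conversions
#'
#' CODATA 2018 values. Internal mechanics are carried in the
#' eV / Angstrom / amu / fs system; reporting follows the conventions of the
#' crystallography and THz-spectroscopy literature: wavenumbers in cm^-1,
#' energies in eV per cell or kJ/mol per molecule, pressures in GPa, volumes
#' in Angstrom^3.
#'
#' @format A named list of doubles:
#' \describe{
#'   \item{e_C}{elementary charge in coulomb}
#'   \item{amu_kg}{atomic mass unit in kg}
#'   \item{eps0}{vacuum permittivity in F/m}
#'   \item{c_cm_s}{speed of light in cm/s}
#'   \item{kB_eV}{Boltzmann constant in eV/K}
#'   \item{kB_kJmol}{Boltzmann constant times Avogadro in kJ/(mol K)}
#'   \item{hbar_eVs}{reduced Planck constant in eV s}
#'   \item{eV_per_cm1}{photon energy in eV of a 1 cm^-1 quantum (h c / 1 cm)}
#'   \item{eV_to_kJmol}{eV per particle to kJ/mol}
#'   \item{GPaA3_to_eV}{1 GPa * Angstrom^3 in eV}
#'   \item{freq_cm1}{sqrt(eV / (amu Angstrom^2)) expressed in cm^-1}
#'   \item{acc_A_fs2}{1 eV/(Angstrom amu) as acceleration in Angstrom/fs^2}
#'   \item{ke_eV}{1 amu (Angstrom/fs)^2 in eV (kinetic-energy conversion)}
#'   \item{radfs_per_cm1}{angular frequency in rad/fs of a 1 cm^-1 mode}
#'   \item{eps_lorentz}{prefactor turning (e^2/amu) / (Angstrom^3 (cm^-1)^2)
#'     oscillator terms into a dimensionless permittivity contribution}
#'   \item{e2A_per_eps0_eV}{e^2/(eps0 * Angstrom) in eV, used by the
#'     dipole-fluctuation permittivity prefactor}
#' }
#' @export
phys_const <- local({
  e_C    <- 1.602176634e-19
  amu_kg <- 1.66053906660e-27
  eps0   <- 8.8541878128e-12
  c_m_s  <- 2.99792458e8
  h_Js   <- 6.62607015e-34
  kB_J   <- 1.380649e-23
  NA_mol <- 6.02214076e23

  # sqrt(eV/(amu A^2)) -> angular frequency (rad/s) -> wavenumber (cm^-1)
  w2_SI    <- e_C / (amu_kg * 1e-20)              # (rad/s)^2 per eV/(amu A^2)
  freq_cm1 <- sqrt(w2_SI) / (2 * pi * c_m_s * 100)

  # Lorentz oscillator: (Z~^2 in e^2/amu) / (eps0 * V[A^3] * w^2[(cm^-1)^2])
  eps_lorentz <- (e_C^2 / amu_kg) /
    (eps0 * 1e-30 * (2 * pi * c_m_s * 100)^2)

  list(
    e_C        = e_C,
    amu_kg     = amu_kg,
    eps0       = eps0,
    c_cm_s     = c_m_s * 100,
    kB_eV      = kB_J / e_C,
    kB_kJmol   = kB_J * NA_mol / 1000,
    hbar_eVs   = h_Js / (2 * pi * e_C),
    eV_per_cm1 = h_Js * c_m_s * 100 / e_C,
    eV_to_kJmol = e_C * NA_mol / 1000,
    GPaA3_to_eV = 1e9 * 1e-30 / e_C,
    freq_cm1   = freq_cm1,
    acc_A_fs2  = e_C / (amu_kg * 1e-10) * 1e-30 * 1e10,
    ke_eV      = amu_kg * 1e10 / e_C,
    radfs_per_cm1 = 2 * pi * c_m_s * 100 * 1e-15,
    eps_lorentz = eps_lorentz,
    e2A_per_eps0_eV = e_C^2 / (eps0 * 1e-10) / e_C
  )
})
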