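#' Physical constants used throughout the package
#'
#' Internal units are Angstrom, nanosecond, kcal/mol, elementary charge,
#' Kelvin and amu. `kB` is Boltzmann's constant in kcal/mol/K, `NA` is
#' Avogadro's number in 1/mol.
#'
#' @format A named list with elements `kB` (kcal/mol/K), `avogadro` (1/mol),
#'   `e_charge` (C), `eps0` (F/m), `kB_si` (J/K), `water_viscosity` (Pa s).
#' @export
bk_constants <- list(
  kB       = 0.0019872041,   # kcal/mol/K
  avogadro = 6.02214076e23,  # 1/mol
  e_charge = 1.602176634e-19, # C
  eps0     = 8.8541878128e-12, # F/m
  kB_si    = 1.380649e-23,   # J/K
  water_viscosity = 0.00089  # Pa s at ~300 K
)

#' Thermal energy in kcal/mol
#'
#' @param temperature Temperature in K.
#' @return kB*T in kcal/mol.
#' @export
thermal_energy <- function(temperature = 300) {
  stopifnot(is.numeric(temperature), temperature > 0)
  bk_constants$kB * temperature
}

#' Bjerrum length of an aqueous-like dielectric
#'
#' Distance at which two unit charges interact with thermal energy kB*T:
#' lB = e^2 / (4 pi eps0 epsr kB T). About 7.1 Angstrom in water at 300 K.
#'
#' @param temperature Temperature in K.
#' @param relative_permittivity Relative dielectric constant (default 78.5).
#' @return Bjerrum length in Angstrom.
#' @export
bjerrum_length <- function(temperature = 300, relative_permittivity = 78.5) {
  stopifnot(temperature > 0, relative_permittivity > 0)
  with(bk_constants, {
    lb_m <- e_charge^2 / (4 * pi * eps0 * relative_permittivity *
                            kB_si * temperature)
    lb_m * 1e10
  })
}

#' Debye screening length of a 1:1 electrolyte
#'
#' Returns 1/kappa with kappa^2 = 8 pi lB n, where n is the per-species ion
#' number density implied by the ionic strength. At zero ionic strength the
#' screening length is infinite (`Inf` is returned).
#'
#' @param ionic_strength Ionic strength in mol/L (>= 0).
#' @param temperature Temperature in K.
#' @param relative_permittivity Relative dielectric constant.
#' @return Debye length in Angstrom (`Inf` at zero ionic strength).
#' @examples
#' debye_length(0.15) # about 7.9 Angstrom at 300 K
#' @export
debye_length <- function(ionic_strength, temperature = 300,
                         relative_permittivity = 78.5) {
  if (!is.numeric(ionic_strength) || length(ionic_strength) != 1 ||
      is.na(ionic_strength) || ionic_strength < 0) {
    stop("`ionic_strength` must be a single non-negative number (mol/L)")
  }
  if (ionic_strength == 0) return(Inf)
  lb <- bjerrum_length(temperature, relative_permittivity)
  # number density of each ion species in 1/A^3 (1 L = 1e27 A^3)
  n <- bk_constants$avogadro * ionic_strength * 1e-27
  kappa2 <- 8 * pi * lb * n
  1 / sqrt(kappa2)
}

#' Stokes-Einstein translational diffusion coefficient
#'
#' D = kB T / (6 pi eta r) for a sphere of hydrodynamic radius `radius`.
#'
#' @param radius Effective hydrodynamic radius in Angstrom.
#' @param temperature Temperature in K.
#' @param viscosity Solvent viscosity in Pa s.
#' @return Diffusion coefficient in Angstrom^2/ns.
#' @export
stokes_einstein_dt <- function(radius, temperature = 300,
                               viscosity = bk_constants$water_viscosity) {
  stopifnot(radius > 0, temperature > 0, viscosity > 0)
  d_m2s <- bk_constants$kB_si * temperature /
    (6 * pi * viscosity * radius * 1e-10)
  d_m2s * 1e11  # m^2/s -> A^2/ns
}

#' Stokes-Einstein rotational diffusion coefficient
#'
#' Dr = kB T / (8 pi eta r^3) for a sphere of hydrodynamic radius `radius`.
#'
#' @inheritParams stokes_einstein_dt
#' @return Rotational diffusion coefficient in rad^2/ns.
#' @export
stokes_einstein_dr <- function(radius, temperature = 300,
                               viscosity = bk_constants$water_viscosity) {
  stopifnot(radius > 0, temperature > 0, viscosity > 0)
  dr_s <- bk_constants$kB_si * temperature /
    (8 * pi * viscosity * (radius * 1e-10)^3)
  dr_s * 1e-9  # 1/s -> 1/ns
}
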