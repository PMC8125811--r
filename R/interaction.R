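#' Non-bonded interaction model (constructor: `interaction_model`)
#'
#' Collects the parameters of the pairwise interaction used by the Brownian
#' dynamics generator: screened (Debye-Hueckel) electrostatics between
#' inter-molecular bead pairs, a purely repulsive soft-core excluded-volume
#' term,
#' and an optional Gaussian attraction well anchored at the native ligand
#' site so that a fully-bound basin exists. The soft-core (rather than a
#' hard-core) repulsion keeps forces bounded, which the Euler-Maruyama
#' integrator requires at the default time step.
#'
#' @param ionic_strength 1:1 electrolyte ionic strength in mol/L (>= 0; 0
#'   disables screening).
#' @param temperature Temperature in K.
#' @param relative_permittivity Relative dielectric constant.
#' @param excluded_volume_strength Soft-core repulsion strength in kcal/mol.
#' @param native_well_depth Depth of the native-site well in kcal/mol
#'   (0 disables it).
#' @param native_well_width Gaussian width of the well in Angstrom.
#' @param cutoff Non-bonded cutoff in Angstrom (default 75, half the
#'   standard box).
#' @return An object of class `bk_interaction` with derived fields
#'   `bjerrum_length` (Angstrom), `debye_length` (Angstrom, `Inf` when
#'   unscreened) and `kBT` (kcal/mol).
#' @export
interaction_model <- function(ionic_strength = 0.15, temperature = 300,
                        relative_permittivity = 78.5,
                        excluded_volume_strength = 10,
                        native_well_depth = 0, native_well_width = 6,
                        cutoff = 75) {
  if (ionic_strength < 0) stop("`ionic_strength` must be >= 0")
  if (native_well_depth < 0) stop("`native_well_depth` must be >= 0")
  structure(list(
    ionic_strength = ionic_strength,
    temperature = temperature,
    relative_permittivity = relative_permittivity,
    bjerrum_length = bjerrum_length(temperature, relative_permittivity),
    debye_length = debye_length(ionic_strength, temperature,
                                relative_permittivity),
    kBT = thermal_energy(temperature),
    excluded_volume_strength = excluded_volume_strength,
    native_well_depth = native_well_depth,
    native_well_width = native_well_width,
    cutoff = cutoff
  ), class = "bk_interaction")
}

#' @export
print.bk_interaction <- function(x, ...) {
  cat(sprintf("bk_interaction: I = %g M, T = %g K, lB = %.2f A, lD = %s A\n",
              x$ionic_strength, x$temperature, x$bjerrum_length,
              ifelse(is.finite(x$debye_length),
                     sprintf("%.2f", x$debye_length), "Inf")))
  cat(sprintf("  soft-core eps = %g kcal/mol; native well depth %g kcal/mol, width %g A\n",
              x$excluded_volume_strength, x$native_well_depth,
              x$native_well_width))
  invisible(x)
}

#' Pairwise potential between two beads
#'
#' U(r) = kB*T * lB * qi * qj * exp(-r / lambda_D) / r plus, when `sigma > 0`,
#' a bounded soft-core overlap repulsion eps*(1 - r/sigma)^2 for r < sigma.
#' Symmetric in the two charges and decaying to zero at large separation.
#'
#' @param r Separation(s) in Angstrom (> 0); vectorised.
#' @param qi,qj Bead charges in e.
#' @param interaction An [interaction_model()] object.
#' @param sigma Excluded-volume contact distance (sum of bead radii) in
#'   Angstrom; 0 (default) evaluates the electrostatic term only.
#' @return Potential energy in kcal/mol.
#' @export
pair_potential <- function(r, qi, qj, interaction, sigma = 0) {
  if (any(r <= 0)) stop("`r` must be > 0")
  kBT <- interaction$kBT
  lB <- interaction$bjerrum_length
  lD <- interaction$debye_length
  screen <- if (is.finite(lD)) exp(-r / lD) else rep(1, length(r))
  u <- kBT * lB * qi * qj * screen / r
  if (sigma > 0) {
    eps <- interaction$excluded_volume_strength
    u <- u + ifelse(r < sigma, eps * (1 - r / sigma)^2, 0)
  }
  u
}

#' Smoluchowski diffusion-limited association rate
#'
#' Closed-form rate 4 pi D R for an absorbing sphere of radius R and relative
#' diffusion coefficient D, converted to bimolecular units.
#'
#' @param D Relative diffusion coefficient in Angstrom^2/ns.
#' @param R Absorbing (reaction) radius in Angstrom.
#' @return Rate in 1/M/s.
#' @export
smoluchowski_rate <- function(D, R) {
  stopifnot(D > 0, R > 0)
  k_vol <- 4 * pi * D * R                # A^3/ns
  k_vol * 1e-27 * 1e9 * bk_constants$avogadro
}

#' Debye-Smoluchowski rate for an interacting pair
#'
#' k = 4 pi D N_A / Int_R^Inf exp(U(r)/kBT) r^-2 dr, evaluated by numerical
#' quadrature. Reduces to [smoluchowski_rate()] for U = 0.
#'
#' @param D Relative diffusion coefficient in Angstrom^2/ns.
#' @param R Absorbing radius in Angstrom.
#' @param potential Function of r (Angstrom) returning the pair potential in
#'   kcal/mol.
#' @param kBT Thermal energy in kcal/mol.
#' @return Rate in 1/M/s.
#' @export
debye_smoluchowski_rate <- function(D, R, potential, kBT = thermal_energy()) {
  stopifnot(D > 0, R > 0)
  integrand <- function(r) exp(potential(r) / kBT) / r^2
  I <- stats::integrate(integrand, R, Inf, rel.tol = 1e-9)$value
  k_vol <- 4 * pi * D / I
  k_vol * 1e-27 * 1e9 * bk_constants$avogadro
}
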