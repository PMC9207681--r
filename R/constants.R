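# CODATA 2018 exact/recommended values, SI units.
.k_e <- 1.602176634e-19      # elementary charge, C
.k_kB <- 1.380649e-23        # Boltzmann constant, J/K
.k_NA <- 6.02214076e23       # Avogadro constant, 1/mol
.k_eps0 <- 8.8541878128e-12  # vacuum permittivity, F/m

#' Debye screening length of a symmetric 1:1 electrolyte
#'
#' \deqn{\lambda = \sqrt{\varepsilon_0 \varepsilon_r k_B T / (2 N_A e^2 I)}}
#' with the ionic strength `I` in mol/L.  At 0.15 M, 310 K and
#' \eqn{\varepsilon_r = 80} this evaluates to 8.09 Angstrom, the screening
#' length of a physiological saline at body temperature.
#'
#' @param ionic_strength ionic strength, mol/L (monovalent salt).
#' @param temperature absolute temperature, K.
#' @param relative_permittivity relative dielectric constant of the solvent.
#' @return Debye length in Angstrom.
#' @examples
#' debye_length(0.15, 310, 80) # ~8.09
#' @export
debye_length <- function(ionic_strength, temperature = 310,
                         relative_permittivity = 80) {
  if (any(ionic_strength <= 0) || any(temperature <= 0) ||
      any(relative_permittivity <= 0)) {
    stop("debye_length: all arguments must be positive")
  }
  lam_m <- sqrt(.k_eps0 * relative_permittivity * .k_kB * temperature /
                  (2 * .k_NA * .k_e^2 * ionic_strength * 1000))
  lam_m * 1e10
}

#' Bjerrum length
#'
#' Distance at which two unit charges interact with thermal energy kT:
#' \eqn{l_B = e^2 / (4\pi \varepsilon_0 \varepsilon_r k_B T)}.
#'
#' @inheritParams debye_length
#' @return Bjerrum length in Angstrom.
#' @export
bjerrum_length <- function(temperature = 310, relative_permittivity = 80) {
  if (any(temperature <= 0) || any(relative_permittivity <= 0)) {
    stop("bjerrum_length: all arguments must be positive")
  }
  .k_e^2 / (4 * pi * .k_eps0 * relative_permittivity * .k_kB * temperature) * 1e10
}

# mol/L -> number density in 1/Angstrom^3
.conc_to_A3 <- function(conc_M) conc_M * .k_NA * 1000 / 1e30
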