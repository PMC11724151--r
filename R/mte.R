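# Metabolic theory of ecology (MTE) rate scaling.
#
# A demographic rate Q scales with body mass m and absolute temperature T as
#   Q = b0 * m^a * exp(-E / (k * T))
# with a the allometric exponent, E the activation energy (eV) and k the
# Boltzmann constant in eV/K. The normalisation constant b0 is anchored so
# that Q equals a species-specific reference value v at the reference
# temperature T_ref (taken to be the species' optimum temperature):
#   b0 = v / (m^a * exp(-E / (k * T_ref)))

#' Boltzmann constant in electron-volt per Kelvin
#'
#' Module constant used by all metabolic-scaling computations, so that
#' activation energies are entered in eV (the MTE convention).
#' @export
boltzmann_ev <- 8.617333262e-5

#' Construct an MTE scaling specification
#'
#' One specification per scaled demographic parameter: the reference value
#' `v` observed at reference temperature `T_ref`, the allometric exponent `a`
#' and the activation energy `E`.
#'
#' @param v reference value of the rate at `T_ref` (units of the target rate).
#' @param a dimensionless allometric (mass) exponent.
#' @param E activation energy in eV; positive values make the rate increase
#'   with temperature, negative values make it decrease.
#' @param T_ref reference temperature in Kelvin (> 0).
#' @return an object of class `dynrange_mte_spec`.
#' @export
mte_spec <- function(v, a, E, T_ref) {
  if (!is.finite(T_ref) || T_ref <= 0) {
    dr_stop("dynrange_bad_value", "T_ref must be a positive temperature in K")
  }
  structure(list(v = v, a = a, E = E, T_ref = T_ref),
            class = "dynrange_mte_spec")
}

#' Normalisation constant of an MTE specification
#'
#' `b0 = v / (mass^a * exp(-E/(k*T_ref)))`, chosen so that [mte_rate()]
#' returns the reference value `v` at `T = T_ref`.
#'
#' @param spec an [mte_spec()].
#' @param mass body mass in grams (> 0).
#' @return the normalisation constant `b0`.
#' @export
normalisation_constant <- function(spec, mass) {
  if (!is.finite(mass) || mass <= 0) {
    dr_stop("dynrange_bad_value", "mass must be positive")
  }
  spec$v / (mass^spec$a * exp(-spec$E / (boltzmann_ev * spec$T_ref)))
}

#' Temperature- and mass-scaled rate
#'
#' `Q = b0 * mass^a * exp(-E/(k*T))`; equivalently
#' `Q = v * exp((E/k) * (1/T_ref - 1/T))`. At `T = T_ref` the reference value
#' is recovered exactly.
#'
#' @param spec an [mte_spec()].
#' @param b0 normalisation constant from [normalisation_constant()].
#' @param mass body mass in grams.
#' @param temperature absolute temperature(s) in Kelvin; vector or matrix.
#' @return scaled rate(s), shaped like `temperature`.
#' @export
mte_rate <- function(spec, b0, mass, temperature) {
  if (any(is.finite(temperature) & temperature <= 0)) {
    dr_stop("dynrange_bad_value", "temperature must be positive (Kelvin)")
  }
  b0 * mass^spec$a * exp(-spec$E / (boltzmann_ev * temperature))
}

#' Per-cell demographic fields from body mass and temperature
#'
#' Derives the per-cell reproduction rate, mortality probability, carrying
#' capacity (and Allee threshold, when the species defines one) from the
#' species' reference values and the local temperature grid via MTE scaling.
#' The reference temperature of every scaled parameter is the species'
#' optimum temperature, so all fields equal their reference values where the
#' local temperature equals the optimum.
#'
#' With `use_metabolic_theory = FALSE` the fields are constant at the
#' species' reference values. Mortality is clamped into \[0, 1\] (it is a
#' probability); cells with missing temperature are uninhabitable and get
#' `r = 0`, `K = 0`, `m = 1`.
#'
#' @param species a `dynrange_species` object (see [species_params()]).
#' @param temperature matrix of absolute temperatures in Kelvin; `NA` cells
#'   are uninhabitable.
#' @param use_metabolic_theory logical flag; `FALSE` bypasses the scaling.
#' @return list with matrices `r`, `m_mort`, `K` and, when the species has an
#'   `allee` threshold, `A`.
#' @export
scale_demography <- function(species, temperature, use_metabolic_theory = TRUE) {
  d <- dim(temperature)
  habitable <- is.finite(temperature)
  one_field <- function(v, a, E) {
    if (!use_metabolic_theory) {
      out <- array(v, dim = d)
    } else {
      spec <- mte_spec(v, a, E, species$optimum_temperature)
      b0 <- normalisation_constant(spec, species$mass)
      out <- array(NA_real_, dim = d)
      out[habitable] <- mte_rate(spec, b0, species$mass,
                                 temperature[habitable])
    }
    out
  }
  r <- one_field(species$growrate, species$exponent_growrate,
                 species$activation_energy_growrate)
  m <- one_field(species$bevmort, species$exponent_bevmort,
                 species$activation_energy_bevmort)
  K <- one_field(species$carry, species$exponent_carry,
                 species$activation_energy_carry)
  m <- pmin(pmax(m, 0), 1)
  r[!habitable] <- 0
  K[!habitable] <- 0
  m[!habitable] <- 1
  out <- list(r = r, m_mort = m, K = K)
  if (!is.null(species$allee) && is.finite(species$allee)) {
    A <- one_field(species$allee, species$exponent_carry,
                   species$activation_energy_carry)
    A[!habitable] <- 0
    out$A <- A
  }
  out
}
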