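#' Physical unit system for a motor model
#'
#' The model itself is dimensionless: energies in `kBT`, distances in units
#' of the working stroke `d`, rates in units of the maximal ATP-induced
#' detachment rate `k_ATP = k_ATP_binding * [ATP]`. A `motor_units` object
#' records the physical values needed to convert back and forth.
#'
#' @param K_phys spring constant of the elastic element, pN/nm.
#' @param d_phys working stroke, nm.
#' @param kBT_phys thermal energy, pN nm (about 4.1 at room temperature).
#' @param k_ATP_rate maximal ATP-induced detachment rate
#'   `k_ATP_binding * [ATP]`, 1/s.
#' @return object of class `motor_units`.
#' @export
motor_units <- function(K_phys, d_phys, kBT_phys, k_ATP_rate = 100) {
  vals <- c(K_phys = K_phys, d_phys = d_phys, kBT_phys = kBT_phys,
            k_ATP_rate = k_ATP_rate)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_invalid("units > 0", "all physical constants must be strictly positive")
  structure(as.list(vals), class = "motor_units")
}

#' Dimensionless constants and conversion factors
#'
#' Converts a physical parameter set to the model's dimensionless constants:
#' the stiffness `kappa = K d^2 / kBT` (reported also as `kappa / 2`, the
#' elastic energy stored over one working stroke), and the scales that map
#' dimensionless velocity, force, rate and energy back to physical units.
#'
#' @param units a [motor_units] object.
#' @return list with `kappa`, `half_kappa`, `velocity_scale` (nm/s per
#'   dimensionless unit), `force_scale` (pN), `rate_scale` (1/s),
#'   `energy_scale` (pN nm).
#' @examples
#' # K = 3 pN/nm, d = 8 nm, kBT = 4 pN nm gives kappa/2 = 24
#' nondimensionalize(motor_units(3, 8, 4))$half_kappa
#' @export
nondimensionalize <- function(units) {
  if (!inherits(units, "motor_units")) stop("need a motor_units object")
  kappa <- units$K_phys * units$d_phys^2 / units$kBT_phys
  list(kappa = kappa,
       half_kappa = kappa / 2,
       velocity_scale = units$k_ATP_rate * units$d_phys,
       force_scale = units$kBT_phys / units$d_phys,
       rate_scale = units$k_ATP_rate,
       energy_scale = units$kBT_phys)
}

#' Physical constants from a dimensionless stiffness
#'
#' Inverse of [nondimensionalize] for the stiffness: returns the physical
#' spring constant that reproduces a given dimensionless `kappa` at the
#' stated stroke and thermal energy.
#'
#' @param kappa dimensionless stiffness `K d^2 / kBT`.
#' @param d_phys working stroke, nm.
#' @param kBT_phys thermal energy, pN nm.
#' @export
redimensionalize_stiffness <- function(kappa, d_phys, kBT_phys) {
  if (kappa <= 0 || d_phys <= 0 || kBT_phys <= 0)
    stop_invalid("units > 0", "all inputs must be strictly positive")
  kappa * kBT_phys / d_phys^2
}
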