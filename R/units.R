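# Physical constants (CODATA): Boltzmann constant in kcal/mol/K and the
# factor converting kcal/mol/A^2 to N/m.
.kB_kcal_mol_K <- 1.380649e-23 * 6.02214076e23 / 4184
.kcalmolA2_to_N_m <- 4184 / 6.02214076e23 / 1e-20

#' Unit system for stiffness calculations
#'
#' Bundles the temperature, the thermal energy kBT and the factor converting
#' model spring-constant units (kcal/mol/A^2, the units of \code{gamma}) to
#' SI N/m. Both stiffness observables are invariant to the temperature in
#' model units — kBT cancels between numerator and denominator — so the
#' temperature only sets the absolute scale of per-mode deformation
#' amplitudes.
#'
#' @param temperature Temperature in kelvin (default 298.15).
#' @return Object of class \code{"unit_system"} with fields
#'   \code{temperature} (K), \code{kBT} (kcal/mol) and
#'   \code{to_newton_per_meter} (N/m per kcal/mol/A^2, 0.694769).
#' @export
#' @examples
#' u <- unit_system()
#' u$kBT               # 0.5925 kcal/mol at 298.15 K
#' convert_units(1, u) # 0.694769 N/m
unit_system <- function(temperature = 298.15) {
  stopifnot(is.numeric(temperature), temperature > 0)
  structure(
    list(temperature = temperature,
         kBT = .kB_kcal_mol_K * temperature,
         to_newton_per_meter = .kcalmolA2_to_N_m),
    class = "unit_system"
  )
}

#' @export
print.unit_system <- function(x, ...) {
  cat("Units: T = ", x$temperature, " K, kBT = ",
      format(x$kBT, digits = 6), " kcal/mol, 1 kcal/mol/A^2 = ",
      format(x$to_newton_per_meter, digits = 6), " N/m\n", sep = "")
  invisible(x)
}

#' Convert a spring constant from model units to N/m
#'
#' @param value Spring constant in kcal/mol/A^2.
#' @param units A \code{"unit_system"}.
#' @return Value in N/m.
#' @export
convert_units <- function(value, units = unit_system()) {
  stopifnot(inherits(units, "unit_system"))
  value * units$to_newton_per_meter
}
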