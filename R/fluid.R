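# Built-in dynamic-viscosity table for liquid water at atmospheric pressure.
# Five points spanning 10-40 degC, values in mPa s from standard reference
# tabulations (CRC Handbook); linear interpolation in between.
.water_viscosity_table <- data.frame(
  temperature_K = c(283.15, 293.15, 298.15, 303.15, 313.15),
  viscosity_Pa_s = c(1.3059e-3, 1.0016e-3, 0.8900e-3, 0.7972e-3, 0.6527e-3)
)

#' Dynamic viscosity of water
#'
#' Linear interpolation of a built-in five-point reference table (10-40
#' degC). The filtration experiments the package models are run at 23.0 degC,
#' where the interpolated value is about 0.9346e-3 Pa s.
#'
#' @param temperature Temperature in kelvin. Must lie within \[283, 313.15\].
#' @return Dynamic viscosity in Pa s.
#' @examples
#' water_viscosity(296.15) # 23 degC
#' @export
water_viscosity <- function(temperature) {
  stopifnot(is.numeric(temperature))
  if (any(temperature < 283 | temperature > 313.15)) {
    abort("`temperature` must be within [283, 313.15] K (the built-in table range).",
          class = "poreforce_domain_error")
  }
  tb <- .water_viscosity_table
  stats::approx(tb$temperature_K, tb$viscosity_Pa_s,
                xout = pmax(temperature, 283.15), rule = 1)$y
}

#' Fluid state of the feed water
#'
#' Bundles the temperature-dependent water properties used across the flow
#' and force calculations. Defaults describe the filtration condition of the
#' experiments the package models: 23.0 degC feed water, bulk water
#' self-diffusivity 2.3e-9 m2 s^-1, and water molarity 55.3 mol L^-1
#' (997 g L^-1 / 18.02 g mol^-1).
#'
#' @param temperature Kelvin; must lie in (273, 373).
#' @param viscosity Pa s; defaults to [water_viscosity()] at `temperature`.
#' @param water_bulk_diffusivity m2 s^-1.
#' @param water_molar_concentration mol L^-1.
#' @return An object of class `fluid_state` (a named list).
#' @examples
#' fluid_state()
#' @export
fluid_state <- function(temperature = 296.15,
                        viscosity = NULL,
                        water_bulk_diffusivity = 2.3e-9,
                        water_molar_concentration = 55.3) {
  if (!is.numeric(temperature) || length(temperature) != 1 ||
      temperature <= 273 || temperature >= 373) {
    abort("`temperature` must be a single value in (273, 373) K.",
          class = "poreforce_domain_error")
  }
  viscosity <- viscosity %||% water_viscosity(temperature)
  if (viscosity <= 0) {
    abort("`viscosity` must be positive.", class = "poreforce_domain_error")
  }
  if (water_bulk_diffusivity <= 0 || water_molar_concentration <= 0) {
    abort("Diffusivity and water molarity must be positive.",
          class = "poreforce_domain_error")
  }
  structure(
    list(
      temperature = temperature,
      viscosity = viscosity,
      water_bulk_diffusivity = water_bulk_diffusivity,
      water_molar_concentration = water_molar_concentration
    ),
    class = "fluid_state"
  )
}

#' @export
print.fluid_state <- function(x, ...) {
  cat(sprintf(
    "<fluid_state> T = %.2f K, mu = %.4g Pa s, D_w = %.3g m2/s, [H2O] = %.1f mol/L\n",
    x$temperature, x$viscosity, x$water_bulk_diffusivity,
    x$water_molar_concentration
  ))
  invisible(x)
}
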