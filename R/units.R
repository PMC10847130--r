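#' Convert membrane flux to superficial velocity
#'
#' Membrane flux is conventionally reported in L m^-2 h^-1; the transport
#' equations work in SI superficial velocity (m s^-1). 1 L m^-2 h^-1 =
#' 1/3.6e6 m s^-1.
#'
#' @param flux Flux in L m^-2 h^-1; must be non-negative.
#' @return Superficial velocity in m s^-1.
#' @seealso [si_to_flux()] for the inverse.
#' @examples
#' flux_to_si(60)
#' @export
flux_to_si <- function(flux) {
  stopifnot(is.numeric(flux))
  if (any(flux < 0)) {
    abort("`flux` must be non-negative.", class = "poreforce_domain_error")
  }
  flux / .LMH_PER_M_S
}

#' @rdname flux_to_si
#' @param velocity Superficial velocity in m s^-1; must be non-negative.
#' @export
si_to_flux <- function(velocity) {
  stopifnot(is.numeric(velocity))
  if (any(velocity < 0)) {
    abort("`velocity` must be non-negative.", class = "poreforce_domain_error")
  }
  velocity * .LMH_PER_M_S
}

#' Molar ratios of the feed solution
#'
#' The trace hormone is dosed from an ethanol stock, so the feed carries a
#' large molar excess of ethanol and, of course, of water. This reports the
#' ethanol:hormone and water:hormone molar ratios, both exactly and rounded
#' to the nearest integer power of ten (the convention used to summarise
#' feed composition).
#'
#' @param hormone_conc Hormone concentration, ng L^-1.
#' @param hormone_mw Hormone molecular weight, g mol^-1.
#' @param ethanol_conc Ethanol concentration, mg L^-1.
#' @param ethanol_mw Ethanol molecular weight, g mol^-1 (46.07 by default).
#' @param fluid A [fluid_state()] supplying the water molarity.
#' @return A tibble with one row per ratio: `species`, `molar_concentration`
#'   (mol L^-1), `ratio_to_hormone`, and `ratio_power10` (the ratio rounded
#'   to the nearest power of ten).
#' @examples
#' molar_ratio_report(100, 272.4, 22.5)
#' @export
molar_ratio_report <- function(hormone_conc, hormone_mw,
                               ethanol_conc, ethanol_mw = 46.07,
                               fluid = fluid_state()) {
  vals <- c(hormone_conc, hormone_mw, ethanol_conc, ethanol_mw)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All concentrations and molecular weights must be positive.",
          class = "poreforce_domain_error")
  }
  hormone_M <- hormone_conc * 1e-9 / hormone_mw   # ng/L -> g/L -> mol/L
  ethanol_M <- ethanol_conc * 1e-3 / ethanol_mw   # mg/L -> g/L -> mol/L
  water_M <- fluid$water_molar_concentration
  ratios <- c(ethanol = ethanol_M / hormone_M, water = water_M / hormone_M)
  tibble(
    species = c("ethanol", "water"),
    molar_concentration = c(ethanol_M, water_M),
    ratio_to_hormone = unname(ratios),
    ratio_power10 = 10^round(log10(unname(ratios)))
  )
}
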