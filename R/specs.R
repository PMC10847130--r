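#' Membrane specification
#'
#' Geometry of one nanoporous membrane: cylindrical pores of diameter
#' `pore_diameter` running through a layer of thickness `thickness`, open
#' area fraction `porosity`, and tortuosity factor `tortuosity` (1 for
#' perfectly straight pores). All lengths in metres.
#'
#' @param name Label.
#' @param pore_diameter Pore diameter d_p, m.
#' @param thickness Membrane (pore) length L, m.
#' @param porosity Open-area fraction, in (0, 1). May be omitted when
#'   `pore_areal_density` is given, in which case it is derived via
#'   [porosity_from_pore_density()].
#' @param tortuosity Tortuosity factor alpha >= 1 (default 1.2, typical of
#'   vertically aligned carbon-nanotube arrays).
#' @param active_area Membrane area exposed to the feed, m2 (optional).
#' @param pore_areal_density Number of pores per m2 (optional). When both
#'   this and `porosity` are supplied they must agree to 1e-12 relative.
#' @return An object of class `membrane_spec`.
#' @examples
#' membrane_spec("vacnt_1p7", 1.7e-9, 50e-6, porosity = 0.034)
#' @export
membrane_spec <- function(name, pore_diameter, thickness,
                          porosity = NULL, tortuosity = 1.2,
                          active_area = NA_real_,
                          pore_areal_density = NULL) {
  if (pore_diameter <= 0 || thickness <= 0) {
    abort("`pore_diameter` and `thickness` must be positive.",
          class = "poreforce_domain_error")
  }
  if (tortuosity < 1) {
    abort("`tortuosity` must be >= 1.", class = "poreforce_domain_error")
  }
  if (is.null(porosity)) {
    if (is.null(pore_areal_density)) {
      abort("Supply `porosity` or `pore_areal_density`.",
            class = "poreforce_domain_error")
    }
    porosity <- porosity_from_pore_density(pore_areal_density, pore_diameter)
  }
  if (porosity <= 0 || porosity >= 1) {
    abort("`porosity` must lie in (0, 1).", class = "poreforce_domain_error")
  }
  if (!is.null(pore_areal_density)) {
    eps_check <- porosity_from_pore_density(pore_areal_density, pore_diameter)
    if (abs(eps_check - porosity) > 1e-12 * porosity) {
      abort(sprintf(
        "`pore_areal_density` implies porosity %.6g, inconsistent with supplied %.6g.",
        eps_check, porosity
      ), class = "poreforce_consistency_error")
    }
  }
  structure(
    list(
      name = name, pore_diameter = pore_diameter, thickness = thickness,
      porosity = porosity, tortuosity = tortuosity,
      active_area = active_area,
      pore_areal_density = pore_areal_density
    ),
    class = "membrane_spec"
  )
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat(sprintf(
    "<membrane_spec> %s: d_p = %.2g nm, L = %.3g um, eps = %.3g, alpha = %.2f\n",
    x$name, x$pore_diameter * 1e9, x$thickness * 1e6, x$porosity, x$tortuosity
  ))
  invisible(x)
}

#' Solute specification
#'
#' One micropollutant treated as an equivalent sphere: hydrodynamic diameter
#' `hydrodynamic_diameter` and a Hamaker constant for the solute/pore-wall
#' pair. The `contact_gap` is the surface separation at which wall adhesion
#' is balanced by short-range electron-cloud repulsion (about 0.3 nm for
#' molecules against a carbon nanotube wall).
#'
#' @param name Label (e.g. "E2").
#' @param molecular_weight g mol^-1.
#' @param hydrodynamic_diameter d_SH, m.
#' @param hamaker_constant H, J; default 2.8e-20 J, calibrated so that the
#'   sphere-wall van der Waals force for a 0.8 nm hormone at a 0.3 nm gap is
#'   about 110 pN (the value reported for 17beta-estradiol against a carbon
#'   nanotube wall).
#' @param contact_gap Equilibrium surface separation, m (default 0.3 nm).
#' @return An object of class `solute_spec`.
#' @examples
#' solute_spec("E2", 272.4, 0.8e-9)
#' @export
solute_spec <- function(name, molecular_weight, hydrodynamic_diameter,
                        hamaker_constant = 2.8e-20,
                        contact_gap = 0.3e-9) {
  if (hydrodynamic_diameter <= 0) {
    abort("`hydrodynamic_diameter` must be positive.",
          class = "poreforce_domain_error")
  }
  if (hamaker_constant < 0) {
    abort("`hamaker_constant` must be >= 0.", class = "poreforce_domain_error")
  }
  if (contact_gap <= 0) {
    abort("`contact_gap` must be positive.", class = "poreforce_domain_error")
  }
  if (molecular_weight <= 0) {
    abort("`molecular_weight` must be positive.",
          class = "poreforce_domain_error")
  }
  structure(
    list(
      name = name, molecular_weight = molecular_weight,
      hydrodynamic_diameter = hydrodynamic_diameter,
      hamaker_constant = hamaker_constant, contact_gap = contact_gap
    ),
    class = "solute_spec"
  )
}

#' @export
print.solute_spec <- function(x, ...) {
  cat(sprintf(
    "<solute_spec> %s: MW = %.1f g/mol, d_SH = %.2g nm, H = %.3g J, g0 = %.2g nm\n",
    x$name, x$molecular_weight, x$hydrodynamic_diameter * 1e9,
    x$hamaker_constant, x$contact_gap * 1e9
  ))
  invisible(x)
}

#' Operating point of a filtration run
#'
#' Couples a flux to a membrane and derives the mean velocity inside the
#' pores, `pore_velocity = flux_si / porosity`. No tortuosity correction is
#' applied to the velocity: the nominal in-pore velocity assumes all pores
#' are open and straight, which reproduces the velocities reported for
#' VaCNT filtration (2.2e-4 m s^-1 at 27 L m^-2 h^-1 and 3.4% porosity).
#'
#' @param flux Flux, L m^-2 h^-1 (>= 0).
#' @param membrane A [membrane_spec()].
#' @param transmembrane_pressure Optional pressure drop, Pa.
#' @return An object of class `operating_point`.
#' @examples
#' m <- membrane_spec("vacnt_1p7", 1.7e-9, 50e-6, porosity = 0.034)
#' operating_point(27, m)
#' @export
operating_point <- function(flux, membrane, transmembrane_pressure = NULL) {
  stopifnot(inherits(membrane, "membrane_spec"))
  if (flux < 0) {
    abort("`flux` must be non-negative.", class = "poreforce_domain_error")
  }
  structure(
    list(
      flux = flux,
      flux_si = flux_to_si(flux),
      transmembrane_pressure = transmembrane_pressure,
      pore_velocity = flux_to_pore_velocity(flux, membrane),
      membrane = membrane
    ),
    class = "operating_point"
  )
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf(
    "<operating_point> J = %.3g L/m2/h (%.3g m/s superficial), v_pore = %.3g m/s [%s]\n",
    x$flux, x$flux_si, x$pore_velocity, x$membrane$name
  ))
  invisible(x)
}

#' Built-in membrane registry
#'
#' Nominal specifications of the three vertically aligned carbon-nanotube
#' membranes the package models: inner pore diameters 1.7, 2.6 and 3.3 nm;
#' porosity 3.4% for the two smaller diameters and 1.9% for the largest;
#' 50 um nominal thickness (measured heights span 26-69 um); tortuosity 1.2
#' for flow calculations.
#'
#' @return Named list of [membrane_spec()] objects
#'   (`vacnt_1p7`, `vacnt_2p6`, `vacnt_3p3`).
#' @examples
#' default_membranes()$vacnt_1p7
#' @export
default_membranes <- function() {
  list(
    vacnt_1p7 = membrane_spec("vacnt_1p7", 1.7e-9, 50e-6, porosity = 0.034),
    vacnt_2p6 = membrane_spec("vacnt_2p6", 2.6e-9, 50e-6, porosity = 0.034),
    vacnt_3p3 = membrane_spec("vacnt_3p3", 3.3e-9, 50e-6, porosity = 0.019)
  )
}

#' Built-in solute registry
#'
#' Only 17beta-estradiol (E2) ships with defaults: molecular weight
#' 272.4 g mol^-1, hydrodynamic diameter 0.8 nm, and the calibrated
#' hormone-CNT Hamaker constant 2.8e-20 J. Diameters for estrone (E1),
#' testosterone (T) and progesterone (P) are not defaulted and must be
#' supplied by configuration, where the ordering d(E1) < d(E2) < d(T) < d(P)
#' is enforced.
#'
#' @return Named list of [solute_spec()] objects.
#' @examples
#' default_solutes()$E2
#' @export
default_solutes <- function() {
  list(E2 = solute_spec("E2", 272.4, 0.8e-9))
}

#' Look up a membrane or solute by name
#'
#' @param name Registry key.
#' @param registry A named list of specs; defaults to the built-in registry.
#' @return The matching spec.
#' @examples
#' get_membrane("vacnt_1p7")
#' @export
get_membrane <- function(name, registry = default_membranes()) {
  if (!name %in% names(registry)) {
    abort(sprintf("Unknown membrane '%s'. Known: %s.",
                  name, paste(names(registry), collapse = ", ")),
          class = "poreforce_lookup_error")
  }
  registry[[name]]
}

#' @rdname get_membrane
#' @export
get_solute <- function(name, registry = default_solutes()) {
  if (!name %in% names(registry)) {
    abort(sprintf("Unknown solute '%s'. Known: %s.",
                  name, paste(names(registry), collapse = ", ")),
          class = "poreforce_lookup_error")
  }
  registry[[name]]
}

# Enforce the hormone-size ordering when all four steroid hormones are
# configured together (adhesion ranking relies on it).
.check_hormone_ordering <- function(solutes) {
  need <- c("E1", "E2", "T", "P")
  if (all(need %in% names(solutes))) {
    d <- vapply(solutes[need], function(s) s$hydrodynamic_diameter, numeric(1))
    if (!all(diff(d) > 0)) {
      abort("Configured hormone diameters must satisfy d(E1) < d(E2) < d(T) < d(P).",
            class = "poreforce_consistency_error")
    }
  }
  invisible(solutes)
}

#' Read a membrane/solute/fluid configuration file
#'
#' YAML schema (SI units throughout):
#' ```yaml
#' fluid:
#'   temperature: 296.15        # K
#'   viscosity: 9.33e-4         # Pa s (optional; from built-in table if absent)
#' membrane:
#'   vacnt_1p7:
#'     pore_diameter: 1.7e-9    # m
#'     thickness: 5.0e-5        # m
#'     porosity: 0.034          # fraction
#'     tortuosity: 1.2
#'     active_area: 2.0e-4      # m2 (optional)
#' solute:
#'   E2:
#'     molecular_weight: 272.4  # g/mol
#'     hydrodynamic_diameter: 8.0e-10  # m
#'     hamaker_constant: 2.8e-20       # J (optional)
#'     contact_gap: 3.0e-10            # m (optional)
#' ```
#'
#' @param path Path to a YAML file.
#' @return List with elements `fluid` ([fluid_state()]), `membranes` and
#'   `solutes` (named lists merged over the built-in registries).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file '%s' not found.", path),
          class = "poreforce_io_error")
  }
  cfg <- yaml::read_yaml(path)
  fl <- do.call(fluid_state, as.list(cfg$fluid %||% list()))
  membranes <- default_membranes()
  for (nm in names(cfg$membrane %||% list())) {
    membranes[[nm]] <- do.call(
      membrane_spec, c(list(name = nm), cfg$membrane[[nm]])
    )
  }
  solutes <- default_solutes()
  for (nm in names(cfg$solute %||% list())) {
    solutes[[nm]] <- do.call(
      solute_spec, c(list(name = nm), cfg$solute[[nm]])
    )
  }
  .check_hormone_ordering(solutes)
  list(fluid = fl, membranes = membranes, solutes = solutes)
}
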