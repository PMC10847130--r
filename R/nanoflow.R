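#' No-slip Hagen-Poiseuille flow through one pore
#'
#' Volumetric flow rate through a single cylindrical pore with a no-slip
#' wall: Q_HP = pi * dP / (8 mu alpha L) * (d_p/2)^4.
#'
#' @param delta_p Pressure drop across the pore, Pa (>= 0).
#' @param membrane A [membrane_spec()].
#' @param fluid A [fluid_state()].
#' @return Flow rate per pore, m3 s^-1.
#' @examples
#' m <- membrane_spec("m", 1.7e-9, 50e-6, porosity = 0.034)
#' hagen_poiseuille_pore_flow(1e5, m)
#' @export
hagen_poiseuille_pore_flow <- function(delta_p, membrane, fluid = fluid_state()) {
  stopifnot(inherits(membrane, "membrane_spec"))
  if (any(delta_p < 0)) {
    abort("`delta_p` must be non-negative.", class = "poreforce_domain_error")
  }
  pi * delta_p / (8 * fluid$viscosity * membrane$tortuosity * membrane$thickness) *
    (membrane$pore_diameter / 2)^4
}

#' Slip-corrected pore flow
#'
#' Adds the slip enhancement term to the Hagen-Poiseuille flow:
#' Q_slip = pi * dP / (8 mu alpha L) * \[(d_p/2)^4 + 4 b (d_p/2)^3\], with
#' slip length `b`. Reduces to [hagen_poiseuille_pore_flow()] at b = 0.
#'
#' @inheritParams hagen_poiseuille_pore_flow
#' @param slip_length Slip length b, m (>= 0).
#' @return Flow rate per pore, m3 s^-1.
#' @export
slip_pore_flow <- function(delta_p, membrane, slip_length, fluid = fluid_state()) {
  if (any(slip_length < 0)) {
    abort("`slip_length` must be non-negative.", class = "poreforce_domain_error")
  }
  r <- membrane$pore_diameter / 2
  hagen_poiseuille_pore_flow(delta_p, membrane, fluid) *
    (1 + 4 * slip_length / r)
}

#' Flow enhancement factor and slip length
#'
#' For a cylindrical pore the ratio of slip-corrected to no-slip flow is
#' EF = Q_slip / Q_HP = 1 + 8 b / d_p. The two functions are exact inverses.
#'
#' @param slip_length Slip length b, m (>= 0).
#' @param pore_diameter Pore diameter d_p, m (> 0).
#' @return `enhancement_factor()`: dimensionless EF >= 1;
#'   `slip_length_from_enhancement()`: b in m.
#' @examples
#' enhancement_factor(100e-9, 1.7e-9)
#' slip_length_from_enhancement(471.6, 1.7e-9)
#' @export
enhancement_factor <- function(slip_length, pore_diameter) {
  if (any(slip_length < 0) || any(pore_diameter <= 0)) {
    abort("`slip_length` must be >= 0 and `pore_diameter` > 0.",
          class = "poreforce_domain_error")
  }
  1 + 8 * slip_length / pore_diameter
}

#' @rdname enhancement_factor
#' @param ef Enhancement factor (>= 1).
#' @export
slip_length_from_enhancement <- function(ef, pore_diameter) {
  if (any(ef < 1)) {
    abort("`ef` must be >= 1.", class = "poreforce_domain_error")
  }
  (ef - 1) * pore_diameter / 8
}

#' Membrane permeability from flux and pressure
#'
#' Lp = J / dP with dP expressed in bar, the membrane community's
#' L m^-2 h^-1 bar^-1 convention.
#'
#' @param flux Flux, L m^-2 h^-1.
#' @param delta_p Transmembrane pressure, Pa (> 0).
#' @return Permeability, L m^-2 h^-1 bar^-1.
#' @examples
#' permeability(30, 2e5)
#' @export
permeability <- function(flux, delta_p) {
  if (any(delta_p <= 0)) {
    abort("`delta_p` must be positive.", class = "poreforce_domain_error")
  }
  flux / (delta_p / .PA_PER_BAR)
}

#' Mean velocity inside the pores
#'
#' v = (J / 3.6e6) / porosity: the superficial velocity divided by the open
#' area fraction, assuming all pores conduct. No tortuosity correction is
#' applied (tortuosity enters the flow-resistance and residence-time
#' expressions instead).
#'
#' @param flux Flux, L m^-2 h^-1 (>= 0).
#' @param membrane A [membrane_spec()], or a bare porosity in (0, 1).
#' @return Pore velocity, m s^-1.
#' @examples
#' flux_to_pore_velocity(27, 0.034)
#' @export
flux_to_pore_velocity <- function(flux, membrane) {
  eps <- if (inherits(membrane, "membrane_spec")) membrane$porosity else membrane
  if (any(eps <= 0) || any(eps >= 1)) {
    abort("Porosity must lie in (0, 1).", class = "poreforce_domain_error")
  }
  flux_to_si(flux) / eps
}

#' Porosity from pore areal density
#'
#' eps = density * pi d_p^2 / 4 for cylindrical pores.
#'
#' @param pore_areal_density Pores per m2 (>= 0).
#' @param pore_diameter Pore diameter, m (> 0).
#' @return Porosity fraction; errors if the result reaches 1.
#' @export
porosity_from_pore_density <- function(pore_areal_density, pore_diameter) {
  if (any(pore_areal_density < 0) || any(pore_diameter <= 0)) {
    abort("`pore_areal_density` must be >= 0 and `pore_diameter` > 0.",
          class = "poreforce_domain_error")
  }
  eps <- pore_areal_density * pi * pore_diameter^2 / 4
  if (any(eps >= 1)) {
    abort("Implied porosity >= 1: pore density inconsistent with diameter.",
          class = "poreforce_consistency_error")
  }
  eps
}

#' Peclet number
#'
#' Pe = v L / D, the ratio of advective to diffusive transport along the
#' pore. Pe > 1 means advection dominates.
#'
#' @param velocity Pore velocity, m s^-1 (>= 0).
#' @param length Transport length, m.
#' @param diffusivity Diffusivity, m2 s^-1 (> 0).
#' @return Dimensionless Peclet number.
#' @examples
#' peclet_number(2.2e-4, 50e-6, 2.3e-9)
#' @export
peclet_number <- function(velocity, length, diffusivity) {
  if (any(diffusivity <= 0)) {
    abort("`diffusivity` must be positive.", class = "poreforce_domain_error")
  }
  if (any(velocity < 0) || any(length < 0)) {
    abort("`velocity` and `length` must be non-negative.",
          class = "poreforce_domain_error")
  }
  velocity * length / diffusivity
}

#' Hydraulic residence time in the pores
#'
#' tau = alpha L / v: the time a fluid element spends traversing the
#' tortuous pore at velocity v.
#'
#' @param membrane A [membrane_spec()].
#' @param velocity Pore velocity, m s^-1 (> 0).
#' @return Residence time, s.
#' @export
hydraulic_residence_time <- function(membrane, velocity) {
  stopifnot(inherits(membrane, "membrane_spec"))
  if (any(velocity <= 0)) {
    abort("`velocity` must be positive.", class = "poreforce_domain_error")
  }
  membrane$tortuosity * membrane$thickness / velocity
}

#' Stokes-Einstein diffusivity
#'
#' D = k_B T / (3 pi mu d) for an equivalent sphere of hydrodynamic
#' diameter d. `diameter_from_diffusivity()` is the exact inverse.
#'
#' @param diameter Hydrodynamic diameter, m (> 0).
#' @param fluid A [fluid_state()].
#' @return Diffusivity, m2 s^-1.
#' @examples
#' stokes_einstein_diffusivity(0.8e-9)
#' @export
stokes_einstein_diffusivity <- function(diameter, fluid = fluid_state()) {
  if (any(diameter <= 0)) {
    abort("`diameter` must be positive.", class = "poreforce_domain_error")
  }
  .kB * fluid$temperature / (3 * pi * fluid$viscosity * diameter)
}

#' @rdname stokes_einstein_diffusivity
#' @param diffusivity Diffusivity, m2 s^-1 (> 0).
#' @export
diameter_from_diffusivity <- function(diffusivity, fluid = fluid_state()) {
  if (any(diffusivity <= 0)) {
    abort("`diffusivity` must be positive.", class = "poreforce_domain_error")
  }
  .kB * fluid$temperature / (3 * pi * fluid$viscosity * diffusivity)
}

#' Characteristic diffusion time over a distance
#'
#' t = x^2 / (2 D), the one-dimensional mean-square-displacement
#' convention.
#'
#' @param distance Distance, m (>= 0).
#' @param diffusivity Diffusivity, m2 s^-1 (> 0).
#' @return Time, s.
#' @export
diffusion_time <- function(distance, diffusivity) {
  if (any(diffusivity <= 0)) {
    abort("`diffusivity` must be positive.", class = "poreforce_domain_error")
  }
  if (any(distance < 0)) {
    abort("`distance` must be non-negative.", class = "poreforce_domain_error")
  }
  distance^2 / (2 * diffusivity)
}

#' Slip length implied by a measured permeability
#'
#' Inverts the slip-corrected pore-flow expression for b given a measured
#' permeability and the pore areal density: the per-pore flow implied by
#' the measurement is compared with the no-slip prediction and the linear
#' slip term solved for. Negative solutions (measured flow below the
#' no-slip prediction) are clamped to 0 with a warning.
#'
#' @param lp Measured permeability, L m^-2 h^-1 bar^-1 (> 0).
#' @param membrane A [membrane_spec()] carrying `pore_areal_density` (or a
#'   porosity from which the density is derived).
#' @param fluid A [fluid_state()].
#' @return Slip length b, m.
#' @export
slip_length_from_permeability <- function(lp, membrane, fluid = fluid_state()) {
  stopifnot(inherits(membrane, "membrane_spec"))
  if (any(lp <= 0)) {
    abort("`lp` must be positive.", class = "poreforce_domain_error")
  }
  density <- membrane$pore_areal_density %||%
    (membrane$porosity / (pi * membrane$pore_diameter^2 / 4))
  # measured per-pore flow at 1 bar
  q_meas <- flux_to_si(lp) / density
  q_hp <- hagen_poiseuille_pore_flow(.PA_PER_BAR, membrane, fluid)
  b <- (q_meas / q_hp - 1) * membrane$pore_diameter / 8
  if (any(b < 0)) {
    warn("Measured permeability below the no-slip prediction; slip length clamped to 0.")
    b <- pmax(b, 0)
  }
  b
}

#' Full flow solution for one membrane and pressure
#'
#' Assembles the per-pore no-slip and slip-corrected flows, enhancement
#' factor, and (when the pore areal density is known) the membrane-scale
#' permeability.
#'
#' @inheritParams slip_pore_flow
#' @return One-row tibble with columns `membrane`, `delta_p`, `slip_length`,
#'   `q_hp`, `q_slip`, `enhancement_factor`, `permeability`.
#' @export
flow_solution <- function(delta_p, membrane, slip_length, fluid = fluid_state()) {
  q_hp <- hagen_poiseuille_pore_flow(delta_p, membrane, fluid)
  q_slip <- slip_pore_flow(delta_p, membrane, slip_length, fluid)
  density <- membrane$pore_areal_density %||%
    (membrane$porosity / (pi * membrane$pore_diameter^2 / 4))
  lp <- if (delta_p > 0) {
    permeability(si_to_flux(q_slip * density), delta_p)
  } else {
    NA_real_
  }
  ef <- enhancement_factor(slip_length, membrane$pore_diameter)
  tibble(
    membrane = membrane$name,
    delta_p = delta_p,
    slip_length = slip_length,
    q_hp = q_hp,
    q_slip = q_slip,
    enhancement_factor = ef,
    permeability = lp
  )
}

#' Transport timescales for one operating point
#'
#' Reports the Peclet number, hydraulic residence time, solute diffusivity
#' (Stokes-Einstein) and the time for the solute to diffuse from the pore
#' centre to the wall.
#'
#' @param op An [operating_point()].
#' @param solute A [solute_spec()].
#' @param fluid A [fluid_state()].
#' @return One-row tibble with `peclet`, `residence_time`,
#'   `solute_diffusivity`, `wall_diffusion_time`.
#' @export
timescale_report <- function(op, solute, fluid = fluid_state()) {
  stopifnot(inherits(op, "operating_point"), inherits(solute, "solute_spec"))
  m <- op$membrane
  d_solute <- stokes_einstein_diffusivity(solute$hydrodynamic_diameter, fluid)
  wall_dist <- max(m$pore_diameter / 2 - solute$hydrodynamic_diameter / 2, 0)
  tibble(
    membrane = m$name,
    solute = solute$name,
    flux = op$flux,
    peclet = peclet_number(op$pore_velocity, m$thickness,
                           fluid$water_bulk_diffusivity),
    residence_time = if (op$pore_velocity > 0) {
      hydraulic_residence_time(m, op$pore_velocity)
    } else {
      Inf
    },
    solute_diffusivity = d_solute,
    wall_diffusion_time = diffusion_time(wall_dist, d_solute)
  )
}
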