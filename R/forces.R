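#' Hydrodynamic drag force on a confined solute
#'
#' Stokes drag F_H = 3 pi mu d_SH v under the plug-flow assumption: in a
#' highly slippery pore the water velocity at the wall equals the mean pore
#' velocity, so a solute sitting at the fluid-wall interface feels the full
#' drag. No hindered-drag (Faxen) correction is applied.
#'
#' @param velocity Water velocity past the solute, m s^-1 (>= 0).
#' @param solute A [solute_spec()].
#' @param fluid A [fluid_state()].
#' @return Drag force, N.
#' @examples
#' drag_force(3e-4, default_solutes()$E2)
#' @export
drag_force <- function(velocity, solute, fluid = fluid_state()) {
  stopifnot(inherits(solute, "solute_spec"))
  if (any(velocity < 0)) {
    abort("`velocity` must be non-negative.", class = "poreforce_domain_error")
  }
  3 * pi * fluid$viscosity * solute$hydrodynamic_diameter * velocity
}

#' Sphere-wall van der Waals adhesive force
#'
#' F_A = H d_SH^3 / (16 g^4), the non-retarded van der Waals attraction
#' between a sphere of diameter d_SH and a flat wall at surface separation
#' g, with Hamaker constant H for the solute-wall pair. For E2 (0.8 nm) at
#' the 0.3 nm contact gap with the default H this is about 110 pN.
#'
#' @param solute A [solute_spec()].
#' @param gap Surface separation g, m (> 0); defaults to the solute's
#'   contact gap.
#' @return Adhesive force, N (vectorised over `gap`).
#' @examples
#' adhesive_force(default_solutes()$E2) * 1e12  # pN
#' @export
adhesive_force <- function(solute, gap = solute$contact_gap) {
  stopifnot(inherits(solute, "solute_spec"))
  if (any(gap <= 0)) {
    abort("`gap` must be positive.", class = "poreforce_domain_error")
  }
  solute$hamaker_constant * solute$hydrodynamic_diameter^3 / (16 * gap^4)
}

#' Short-range repulsive force
#'
#' Electron-cloud repulsion modelled as a Lennard-Jones-wall style power
#' law F_R = C / g^10, with C calibrated per solute so that repulsion
#' balances adhesion exactly at the contact gap g0: F_R(g0) = F_A(g0). The
#' g^-10 decay is steeper than the g^-4 adhesive decay, so the net radial
#' force is attractive for all g > g0 and repulsive inside it.
#'
#' @inheritParams adhesive_force
#' @return Repulsive force, N.
#' @export
repulsive_force <- function(solute, gap) {
  stopifnot(inherits(solute, "solute_spec"))
  if (any(gap <= 0)) {
    abort("`gap` must be positive.", class = "poreforce_domain_error")
  }
  g0 <- solute$contact_gap
  adhesive_force(solute, g0) * (g0 / gap)^10
}

#' Equilibrium surface separation
#'
#' The root of F_A(g) - F_R(g) = 0, located numerically on \[0.05, 5\] nm to
#' a tolerance of 1e-13 m. With the built-in calibration the root equals
#' the solute's contact gap by construction; the numeric search guards
#' user-supplied force overrides.
#'
#' @param solute A [solute_spec()].
#' @return Equilibrium gap, m.
#' @examples
#' equilibrium_gap(default_solutes()$E2) * 1e9  # nm
#' @export
equilibrium_gap <- function(solute) {
  f <- function(g) adhesive_force(solute, g) - repulsive_force(solute, g)
  lo <- 0.05e-9; hi <- 5e-9
  if (sign(f(lo)) == sign(f(hi))) {
    abort("No adhesion-repulsion balance point in [0.05, 5] nm.",
          class = "poreforce_model_error")
  }
  uniroot(f, c(lo, hi), tol = 1e-15)$root
}

#' Friction threshold model
#'
#' The package treats wall friction as Amontons-style: proportional to the
#' contact adhesive load, F_F = mu_f * F_A(contact gap). The proportionality
#' is calibrated once against the observed adsorption threshold for the
#' calibrating solute (E2 on a carbon nanotube wall) and then extends across
#' solutes through their adhesive forces.
#'
#' Two calibration anchors are supported. `"velocity"` (default) anchors on
#' the pore velocity at which E2 adsorption vanishes, 3.0e-4 m s^-1, so the
#' drag threshold is 3 pi mu d_SH v_thr (about 2.11e-15 N at 23 degC —
#' within 5% of the reported 2.2e-3 pN, whose exact value depends on an
#' unreported viscosity). `"force"` anchors directly on the reported
#' threshold force 2.2e-15 N.
#'
#' @param solute Calibrating [solute_spec()] (default E2).
#' @param fluid A [fluid_state()].
#' @param anchor `"velocity"` or `"force"`.
#' @param threshold_velocity Pore velocity anchor, m s^-1.
#' @param drag_threshold Force anchor, N (used when `anchor = "force"`).
#' @return An object of class `threshold_model`: list with `drag_threshold`
#'   (N) and `friction_coefficient` (dimensionless).
#' @examples
#' threshold_model()
#' @export
threshold_model <- function(solute = default_solutes()$E2,
                            fluid = fluid_state(),
                            anchor = c("velocity", "force"),
                            threshold_velocity = 3.0e-4,
                            drag_threshold = 2.2e-15) {
  anchor <- match.arg(anchor)
  fa0 <- adhesive_force(solute)
  if (fa0 <= 0) {
    abort("Calibrating solute must have positive contact adhesion.",
          class = "poreforce_model_error")
  }
  thr <- switch(anchor,
    velocity = drag_force(threshold_velocity, solute, fluid),
    force = drag_threshold
  )
  if (thr <= 0) {
    abort("Calibrated drag threshold must be positive.",
          class = "poreforce_model_error")
  }
  structure(
    list(
      drag_threshold = thr,
      friction_coefficient = thr / fa0,
      anchor = anchor,
      calibrating_solute = solute$name
    ),
    class = "threshold_model"
  )
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf(
    "<threshold_model> anchor = %s (%s): drag threshold %.3g pN, mu_f = %.3g\n",
    x$anchor, x$calibrating_solute, x$drag_threshold * 1e12,
    x$friction_coefficient
  ))
  invisible(x)
}

#' Friction force resisting solute movement along the wall
#'
#' F_F = mu_f * F_A(contact gap) for the given solute: friction grows with
#' the Hamaker constant and (cubically) with the solute diameter, encoding
#' that stickier, larger molecules resist sliding more.
#'
#' @param solute A [solute_spec()].
#' @param model A [threshold_model()].
#' @return Friction force, N.
#' @export
friction_threshold <- function(solute, model = threshold_model()) {
  stopifnot(inherits(model, "threshold_model"))
  model$friction_coefficient * adhesive_force(solute)
}

#' Classify the adsorption regime
#'
#' A confined solute appears adsorbed when the drag pushing it along the
#' pore cannot overcome wall friction: regime is `"adsorptive"` iff
#' F_H < F_F, else `"advective-clearance"`. Monotone in velocity: lowering
#' the flux can only move a solute toward adsorption.
#'
#' @param f_h Drag force, N (>= 0); vectorised.
#' @param f_f Friction force, N (>= 0).
#' @return Character vector of regimes.
#' @export
classify_regime <- function(f_h, f_f) {
  if (any(f_h < 0) || any(f_f < 0)) {
    abort("Forces must be non-negative.", class = "poreforce_domain_error")
  }
  ifelse(f_h < f_f, "adsorptive", "advective-clearance")
}

#' Full force profile for one solute, membrane and flux
#'
#' Evaluates the four forces at the operating point: drag at the pore
#' velocity, adhesion and repulsion at the equilibrium gap, the friction
#' threshold, the adhesion/drag ratio, and the resulting regime.
#'
#' @param membrane A [membrane_spec()].
#' @param solute A [solute_spec()].
#' @param flux Flux, L m^-2 h^-1 (vectorised).
#' @param fluid A [fluid_state()].
#' @param model A [threshold_model()].
#' @return Tibble of class `force_profile`, one row per flux, with columns
#'   `membrane`, `solute`, `flux`, `velocity` (m s^-1), `f_drag`,
#'   `f_adhesive`, `f_repulsive`, `f_friction` (all N), `equilibrium_gap`
#'   (m), `adhesion_drag_ratio`, `regime`.
#' @examples
#' force_profile(default_membranes()$vacnt_1p7, default_solutes()$E2, 27)
#' @export
force_profile <- function(membrane, solute, flux,
                          fluid = fluid_state(),
                          model = threshold_model(fluid = fluid)) {
  stopifnot(inherits(membrane, "membrane_spec"), inherits(solute, "solute_spec"))
  v <- flux_to_pore_velocity(flux, membrane)
  g_eq <- equilibrium_gap(solute)
  f_h <- drag_force(v, solute, fluid)
  f_a <- adhesive_force(solute, g_eq)
  f_r <- repulsive_force(solute, g_eq)
  f_f <- friction_threshold(solute, model)
  out <- tibble(
    membrane = membrane$name,
    solute = solute$name,
    flux = flux,
    velocity = v,
    f_drag = f_h,
    f_adhesive = f_a,
    f_repulsive = f_r,
    f_friction = f_f,
    equilibrium_gap = g_eq,
    adhesion_drag_ratio = ifelse(f_h > 0, f_a / f_h, Inf),
    regime = classify_regime(f_h, f_f)
  )
  class(out) <- c("force_profile", class(out))
  out
}

#' Flux at which the regime flips
#'
#' The flux where drag equals the friction threshold for the given solute
#' and membrane: below it the solute is adsorptive, above it cleared. Solved
#' in closed form from F_H = F_F (drag is linear in flux).
#'
#' @inheritParams force_profile
#' @return Transition flux, L m^-2 h^-1.
#' @examples
#' regime_transition_flux(default_membranes()$vacnt_1p7, default_solutes()$E2)
#' @export
regime_transition_flux <- function(membrane, solute,
                                   fluid = fluid_state(),
                                   model = threshold_model(fluid = fluid)) {
  f_f <- friction_threshold(solute, model)
  v_star <- f_f / (3 * pi * fluid$viscosity * solute$hydrodynamic_diameter)
  si_to_flux(v_star * membrane$porosity)
}

#' Rank solutes by contact adhesive force
#'
#' With a uniform Hamaker constant the adhesive force scales with the cube
#' of the solute diameter, so the ranking follows molecular size. For the
#' four steroid hormones with d(E1) < d(E2) < d(T) < d(P) the predicted
#' order is P > T > E2 > E1, matching the observed adsorbed-mass order.
#'
#' @param solutes A named list of [solute_spec()] objects.
#' @return Tibble sorted by descending adhesive force: `solute`,
#'   `hydrodynamic_diameter`, `hamaker_constant`, `f_adhesive` (N),
#'   `f_adhesive_pN`, `rank`.
#' @export
rank_by_adhesion <- function(solutes) {
  if (length(solutes) < 1) {
    abort("Need at least one solute.", class = "poreforce_domain_error")
  }
  bad <- names(solutes)[!vapply(solutes, inherits, logical(1), "solute_spec")]
  if (length(bad) > 0) {
    abort(sprintf("Not solute_spec objects: %s.", paste(bad, collapse = ", ")),
          class = "poreforce_domain_error")
  }
  purrr::map_dfr(solutes, function(s) {
    tibble(
      solute = s$name,
      hydrodynamic_diameter = s$hydrodynamic_diameter,
      hamaker_constant = s$hamaker_constant,
      f_adhesive = adhesive_force(s)
    )
  }) |>
    dplyr::arrange(dplyr::desc(.data$f_adhesive)) |>
    dplyr::mutate(f_adhesive_pN = .data$f_adhesive * 1e12,
                  rank = dplyr::row_number())
}
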