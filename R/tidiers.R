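#' Tidy a force profile into long format
#'
#' One row per force per operating point, with magnitudes in both N and pN
#' (the display unit for molecular-scale forces).
#'
#' @param x A `force_profile` from [force_profile()].
#' @param ... Unused.
#' @return Tibble with `membrane`, `solute`, `flux`, `velocity`, `force`
#'   (drag/adhesive/repulsive/friction), `newtons`, `piconewtons`,
#'   `regime`.
#' @method tidy force_profile
#' @export
tidy.force_profile <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(
      cols = c("f_drag", "f_adhesive", "f_repulsive", "f_friction"),
      names_to = "force", names_prefix = "f_", values_to = "newtons"
    ) |>
    dplyr::mutate(piconewtons = .data$newtons * 1e12) |>
    dplyr::select("membrane", "solute", "flux", "velocity",
                  "force", "newtons", "piconewtons", "regime")
}

#' One-row summary of a force profile
#'
#' @param x A `force_profile`.
#' @param ... Unused.
#' @return Tibble with the flux range, drag range (pN), the constant
#'   adhesive force (pN), friction threshold (pN), and the share of
#'   operating points classified adsorptive.
#' @method glance force_profile
#' @export
glance.force_profile <- function(x, ...) {
  tibble(
    membrane = x$membrane[1],
    solute = x$solute[1],
    n_fluxes = nrow(x),
    flux_min = min(x$flux),
    flux_max = max(x$flux),
    f_drag_min_pN = min(x$f_drag) * 1e12,
    f_drag_max_pN = max(x$f_drag) * 1e12,
    f_adhesive_pN = x$f_adhesive[1] * 1e12,
    f_friction_pN = x$f_friction[1] * 1e12,
    frac_adsorptive = mean(x$regime == "adsorptive")
  )
}

#' @method tidy breakthrough_curve
#' @export
tidy.breakthrough_curve <- function(x, ...) {
  as_tibble(x) |>
    dplyr::mutate(
      label = attr(x, "label"),
      flux = attr(x, "flux")
    )
}

#' @method glance breakthrough_curve
#' @export
glance.breakthrough_curve <- function(x, ...) {
  pl <- saturation_plateau(x)
  tibble(
    label = attr(x, "label"),
    flux = attr(x, "flux"),
    n_samples = nrow(x),
    final_volume = max(x$volume_mL),
    plateau = pl$plateau,
    classification = pl$classification,
    censored_fraction = mean(x$below_detection)
  )
}

#' Plot a breakthrough curve
#'
#' Relative permeate concentration against cumulative permeate volume, with
#' detection-limit-censored points marked.
#'
#' @param object A [breakthrough_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot breakthrough_curve
#' @export
autoplot.breakthrough_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$volume_mL, y = .data$c_over_c0)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$below_detection), size = 2) +
    ggplot2::scale_shape_manual(
      values = c(`FALSE` = 16, `TRUE` = 1),
      labels = c(`FALSE` = "quantified", `TRUE` = "< detection limit"),
      name = NULL
    ) +
    ggplot2::labs(
      x = "Permeate volume (mL)",
      y = expression(c / c[0]),
      title = attr(object, "label")
    ) +
    ggplot2::coord_cartesian(ylim = c(0, NA)) +
    ggplot2::theme_minimal()
}

#' Drag force and regime across a flux sweep
#'
#' The flux - velocity - drag relationship for one solute and membrane,
#' with the friction threshold marked: the crossing is the predicted
#' adsorption/clearance transition.
#'
#' @param profile A `force_profile` with several fluxes.
#' @return A ggplot.
#' @export
plot_force_flux <- function(profile) {
  stopifnot(inherits(profile, "force_profile"))
  thr_pN <- profile$f_friction[1] * 1e12
  ggplot2::ggplot(as_tibble(profile),
                  ggplot2::aes(x = .data$flux, y = .data$f_drag * 1e12)) +
    ggplot2::geom_hline(yintercept = thr_pN, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$regime), size = 2) +
    ggplot2::labs(
      x = expression("Flux (L" ~ m^-2 ~ h^-1 * ")"),
      y = expression(F[H] ~ "(pN)"),
      colour = NULL,
      title = sprintf("%s on %s", profile$solute[1], profile$membrane[1])
    ) +
    ggplot2::theme_minimal()
}

#' Adsorbed mass against drag force
#'
#' The headline regime plot: measured specific adsorbed mass against the
#' drag force at each flux, with the friction threshold marked.
#'
#' @param table Output of [regime_table()].
#' @param model A [threshold_model()] supplying the threshold line.
#' @return A ggplot.
#' @export
plot_regime_map <- function(table, model = threshold_model()) {
  ggplot2::ggplot(table,
                  ggplot2::aes(x = .data$f_drag_pN, y = .data$q_ads_A)) +
    ggplot2::geom_vline(xintercept = model$drag_threshold * 1e12,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$q_ads_A - .data$sigma,
                   ymax = .data$q_ads_A + .data$sigma),
      width = 0
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$regime), size = 2.5) +
    ggplot2::labs(
      x = expression(F[H] ~ "(pN)"),
      y = expression(q[ads * "," * A] ~ "(ng" ~ cm^-2 * ")"),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
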