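#' Apparent permeability and diffusivity from a diffusion-cell time series
#'
#' Quasi-steady two-compartment analysis of a static diffusion-cell
#' experiment: the feed-permeate concentration difference decays as
#' ln(dC(t)/dC(0)) = -(2 A P / V) t, fitted by unweighted least squares on
#' the log-transformed difference. The apparent pore diffusivity follows as
#' D = P L alpha / eps (partition coefficient assumed 1). The result is
#' flagged `apparent`: in thick low-porosity membranes boundary-layer and
#' accessibility effects mean the pore diffusivity is not accurately
#' determined this way.
#'
#' @param data Data frame with columns `time_h`, `feed_ng_per_L`,
#'   `permeate_ng_per_L`; at least three time points.
#' @param cell_volume Volume of each half-cell, m3.
#' @param exposed_area Membrane area exposed between the half cells, m2.
#' @param membrane A [membrane_spec()].
#' @return One-row tibble of class `diffusion_cell_fit` with
#'   `permeability_m_s` (apparent solute permeability P, m s^-1),
#'   `diffusivity_m2_s` (apparent pore diffusivity), `rate_constant_per_h`,
#'   `n_points`, `r_squared`, `apparent` (always TRUE).
#' @export
diffusion_cell_estimate <- function(data, cell_volume, exposed_area, membrane) {
  stopifnot(inherits(membrane, "membrane_spec"))
  need <- c("time_h", "feed_ng_per_L", "permeate_ng_per_L")
  if (!all(need %in% names(data))) {
    abort(sprintf("`data` must have columns %s.", paste(need, collapse = ", ")),
          class = "poreforce_io_error")
  }
  if (nrow(data) < 3) {
    abort("Need at least 3 time points.", class = "poreforce_domain_error")
  }
  if (cell_volume <= 0 || exposed_area <= 0) {
    abort("`cell_volume` and `exposed_area` must be positive.",
          class = "poreforce_domain_error")
  }
  data <- dplyr::arrange(as_tibble(data), .data$time_h)
  dC <- data$feed_ng_per_L - data$permeate_ng_per_L
  if (any(dC <= 0)) {
    abort("Feed-permeate difference must stay positive over the series.",
          class = "poreforce_domain_error")
  }
  # tolerate noise, but flag a clearly falling permeate
  if (any(diff(data$permeate_ng_per_L) < -0.05 * max(data$permeate_ng_per_L))) {
    warn("Permeate series is non-monotone beyond noise; fit may be unreliable.")
  }
  if (all(data$permeate_ng_per_L == 0)) {
    k <- 0; r2 <- NA_real_
  } else {
    y <- log(dC / dC[1])
    fit <- lm(y ~ 0 + time_h, data = data.frame(time_h = data$time_h, y = y))
    k <- -unname(coef(fit)[1])              # per hour
    r2 <- summary(fit)$r.squared
  }
  p_app <- k / 3600 * cell_volume / (2 * exposed_area)  # m s^-1
  d_app <- p_app * membrane$thickness * membrane$tortuosity / membrane$porosity
  structure(
    tibble(
      permeability_m_s = p_app,
      diffusivity_m2_s = d_app,
      rate_constant_per_h = k,
      n_points = nrow(data),
      r_squared = r2,
      apparent = TRUE
    ),
    class = c("diffusion_cell_fit", class(tibble())))
}

#' @method glance diffusion_cell_fit
#' @export
glance.diffusion_cell_fit <- function(x, ...) {
  tibble(
    permeability_m_s = x$permeability_m_s,
    diffusivity_m2_s = x$diffusivity_m2_s,
    r_squared = x$r_squared,
    n = x$n_points
  )
}
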