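#' Construct a breakthrough curve
#'
#' A breakthrough curve records the relative permeate concentration c/c0
#' against cumulative permeate volume for one filtration run. Input data
#' may carry either `c_over_c0` or the absolute permeate concentration
#' `c_ngL`; the other is derived from the feed concentration. Values below
#' the detection limit are set to the limit and flagged
#' (`below_detection`), giving a conservative adsorbed-mass estimate with a
#' transparent censoring record.
#'
#' @param data Data frame with column `volume_mL` (strictly increasing,
#'   >= 0) and `c_over_c0` and/or `c_ngL`.
#' @param feed_concentration Feed concentration c0, ng L^-1 (> 0).
#' @param membrane_area Membrane area, cm2 (> 0).
#' @param flux Flux during the run, L m^-2 h^-1.
#' @param label Curve label.
#' @param detection_limit Quantification limit, ng L^-1 (default 0.2).
#' @return Tibble of class `breakthrough_curve` with columns `volume_mL`,
#'   `c_over_c0`, `c_ngL`, `below_detection`, and attributes
#'   `feed_concentration`, `membrane_area`, `flux`, `label`,
#'   `detection_limit`.
#' @export
breakthrough_curve <- function(data, feed_concentration, membrane_area,
                               flux = NA_real_, label = "",
                               detection_limit = 0.2) {
  data <- as_tibble(data)
  if (!"volume_mL" %in% names(data)) {
    abort("`data` must have a `volume_mL` column.", class = "poreforce_parse_error")
  }
  if (!is.numeric(feed_concentration) || feed_concentration <= 0) {
    abort("`feed_concentration` must be positive.", class = "poreforce_parse_error")
  }
  if (!is.numeric(membrane_area) || membrane_area <= 0) {
    abort("`membrane_area` must be positive.", class = "poreforce_parse_error")
  }
  v <- data$volume_mL
  if (any(v < 0)) {
    abort(sprintf("Negative permeate volume at row %d.", which(v < 0)[1]),
          class = "poreforce_parse_error")
  }
  if (any(diff(v) <= 0)) {
    i <- which(diff(v) <= 0)[1] + 1
    abort(sprintf("Permeate volumes must be strictly increasing; violated at row %d (%.4g mL).",
                  i, v[i]),
          class = "poreforce_parse_error")
  }
  has_rel <- "c_over_c0" %in% names(data)
  has_abs <- "c_ngL" %in% names(data)
  if (!has_rel && !has_abs) {
    abort("`data` must have a `c_over_c0` or `c_ngL` column.",
          class = "poreforce_parse_error")
  }
  if (has_rel && has_abs) {
    off <- abs(data$c_over_c0 * feed_concentration - data$c_ngL) >
      1e-9 * pmax(data$c_ngL, detection_limit)
    if (any(off)) {
      abort(sprintf("`c_over_c0` and `c_ngL` disagree at row %d.", which(off)[1]),
            class = "poreforce_parse_error")
    }
  }
  c_abs <- if (has_abs) data$c_ngL else data$c_over_c0 * feed_concentration
  if (any(c_abs < 0)) {
    abort(sprintf("Negative concentration at row %d.", which(c_abs < 0)[1]),
          class = "poreforce_parse_error")
  }
  below <- c_abs < detection_limit
  c_abs[below] <- detection_limit
  out <- tibble(
    volume_mL = v,
    c_over_c0 = c_abs / feed_concentration,
    c_ngL = c_abs,
    below_detection = below
  )
  structure(
    out,
    class = c("breakthrough_curve", class(tibble())),
    feed_concentration = feed_concentration,
    membrane_area = membrane_area,
    flux = flux,
    label = label,
    detection_limit = detection_limit
  )
}

#' Read a breakthrough curve from delimited text
#'
#' The file is a comma-separated table with a header row and columns
#' `volume_mL` plus `c_over_c0` or `c_ngL`. Run metadata may be carried in
#' leading comment lines of the form `# key: value` with keys
#' `c0_ng_per_L`, `area_cm2`, `flux_lmh`, `label`, `detection_limit_ng_L`;
#' function arguments override file metadata.
#'
#' @param path File path.
#' @param feed_concentration,membrane_area,flux,label,detection_limit
#'   Optional overrides of file metadata (see [breakthrough_curve()]).
#' @return A [breakthrough_curve()].
#' @export
read_breakthrough <- function(path, feed_concentration = NULL,
                              membrane_area = NULL, flux = NULL,
                              label = NULL, detection_limit = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File '%s' not found.", path), class = "poreforce_io_error")
  }
  lines <- readLines(path)
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^\\s*#\\s*", "", ml)
    if (grepl(":", kv)) {
      key <- trimws(sub(":.*$", "", kv))
      val <- trimws(sub("^[^:]*:", "", kv))
      meta[[key]] <- val
    }
  }
  num_meta <- function(key) if (!is.null(meta[[key]])) as.numeric(meta[[key]]) else NULL
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(tab) == 0) {
    abort(sprintf("No data rows in '%s'.", path), class = "poreforce_parse_error")
  }
  c0 <- feed_concentration %||% num_meta("c0_ng_per_L")
  area <- membrane_area %||% num_meta("area_cm2")
  if (is.null(c0) || is.null(area)) {
    abort("Feed concentration and membrane area must come from arguments or '# key: value' metadata lines.",
          class = "poreforce_parse_error")
  }
  breakthrough_curve(
    tab,
    feed_concentration = c0,
    membrane_area = area,
    flux = flux %||% num_meta("flux_lmh") %||% NA_real_,
    label = label %||% meta[["label"]] %||% "",
    detection_limit = detection_limit %||% num_meta("detection_limit_ng_L") %||% 0.2
  )
}

#' Write a breakthrough curve as delimited text
#'
#' Emits the same schema [read_breakthrough()] consumes, metadata comment
#' lines included; output is deterministic (byte-identical for identical
#' curves).
#'
#' @param curve A [breakthrough_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_breakthrough <- function(curve, path) {
  stopifnot(inherits(curve, "breakthrough_curve"))
  hdr <- c(
    sprintf("# c0_ng_per_L: %.15g", attr(curve, "feed_concentration")),
    sprintf("# area_cm2: %.15g", attr(curve, "membrane_area")),
    sprintf("# flux_lmh: %.15g", attr(curve, "flux")),
    sprintf("# label: %s", attr(curve, "label")),
    sprintf("# detection_limit_ng_L: %.15g", attr(curve, "detection_limit")),
    "volume_mL,c_over_c0,c_ngL,below_detection"
  )
  rows <- sprintf("%.15g,%.15g,%.15g,%s",
                  curve$volume_mL, curve$c_over_c0, curve$c_ngL,
                  ifelse(curve$below_detection, "TRUE", "FALSE"))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# Trapezoid mass balance over [0, v_end], with linear interpolation of the
# final partial interval. Returns the quadrature weights alongside so the
# caller can propagate per-point uncertainty.
.trapezoid_deficit <- function(volume, deficit, v_end) {
  keep <- volume <= v_end + 1e-12
  v <- volume[keep]
  d <- deficit[keep]
  if (max(volume) > v_end && max(v) < v_end) {
    # interpolate the curve at the evaluation volume (exact for
    # piecewise-linear data)
    j <- findInterval(v_end, volume)
    frac <- (v_end - volume[j]) / (volume[j + 1] - volume[j])
    v <- c(v, v_end)
    d <- c(d, deficit[j] + frac * (deficit[j + 1] - deficit[j]))
  }
  n <- length(v)
  w <- numeric(n)
  if (n >= 2) {
    dv <- diff(v)
    w[1] <- dv[1] / 2
    w[n] <- dv[n - 1] / 2
    if (n > 2) w[2:(n - 1)] <- (dv[-(n - 1)] + dv[-1]) / 2
  }
  list(value = sum(w * d), weights = w, volume = v, n = n, keep = keep)
}

#' Specific adsorbed mass from a breakthrough curve
#'
#' Mass balance over the permeate: the solute mass lost to the membrane per
#' unit area is q = (1/A) * integral of (c0 - c) dV, evaluated by trapezoid
#' quadrature on the sampled grid (exact for piecewise-linear curves) up to
#' the evaluation volume. c/c0 is not clipped at 1, so desorption appears
#' as negative increments. First-order uncertainty propagation through the
#' quadrature uses per-point concentration uncertainties (default 5%
#' relative, the spread of triplicate scintillation counts).
#'
#' @param curve A [breakthrough_curve()].
#' @param up_to_volume Evaluation volume, mL; defaults to the last sample.
#'   Must not exceed the data range.
#' @param sigma_rel Relative per-point concentration uncertainty.
#' @param sigma Optional absolute per-point uncertainties, ng L^-1
#'   (overrides `sigma_rel`; recycled).
#' @return One-row tibble of class `adsorption_result`: `label`, `flux`,
#'   `q_ads_A` (ng cm^-2), `sigma` (1 s.d., ng cm^-2), `evaluation_volume`
#'   (mL), `censored_fraction`, `n_samples`, `membrane_area`.
#' @examples
#' bt <- breakthrough_curve(
#'   data.frame(volume_mL = c(0, 10, 20), c_over_c0 = c(0, 0.5, 1)),
#'   feed_concentration = 100, membrane_area = 2
#' )
#' specific_adsorbed_mass(bt)
#' @export
specific_adsorbed_mass <- function(curve, up_to_volume = NULL,
                                   sigma_rel = 0.05, sigma = NULL) {
  stopifnot(inherits(curve, "breakthrough_curve"))
  if (nrow(curve) < 2) {
    abort("Need at least two samples to integrate a breakthrough curve.",
          class = "poreforce_domain_error")
  }
  v_end <- up_to_volume %||% max(curve$volume_mL)
  if (v_end > max(curve$volume_mL) + 1e-12) {
    abort(sprintf("Evaluation volume %.4g mL exceeds the data range (%.4g mL).",
                  v_end, max(curve$volume_mL)),
          class = "poreforce_domain_error")
  }
  if (v_end <= min(curve$volume_mL)) {
    abort("Evaluation volume must exceed the first sample volume.",
          class = "poreforce_domain_error")
  }
  c0 <- attr(curve, "feed_concentration")
  area <- attr(curve, "membrane_area")
  c0_mL <- c0 / 1000                      # ng L^-1 -> ng mL^-1
  deficit <- c0_mL * (1 - curve$c_over_c0)
  tz <- .trapezoid_deficit(curve$volume_mL, deficit, v_end)
  q <- tz$value / area
  sig_c <- if (is.null(sigma)) sigma_rel * curve$c_ngL else rep_len(sigma, nrow(curve))
  sig_mL <- sig_c[tz$keep] / 1000
  if (length(sig_mL) < tz$n) sig_mL <- c(sig_mL, sig_mL[length(sig_mL)])
  sig_q <- sqrt(sum((tz$weights * sig_mL)^2)) / area
  used <- curve$below_detection[curve$volume_mL <= v_end + 1e-12]
  out <- tibble(
    label = attr(curve, "label"),
    flux = attr(curve, "flux"),
    q_ads_A = q,
    sigma = sig_q,
    evaluation_volume = v_end,
    censored_fraction = mean(used),
    n_samples = tz$n,
    membrane_area = area
  )
  class(out) <- c("adsorption_result", class(out))
  out
}

#' Subtract the support-membrane contribution
#'
#' The carbon-nanotube layer sits on a microfiltration support that itself
#' adsorbs a flux-independent amount of solute. The membrane's own adsorbed
#' mass is the total minus the support contribution measured at a matched
#' flux; uncertainties add in quadrature. Differences within one combined
#' standard deviation are flagged insignificant.
#'
#' @param q_total,q_support `adsorption_result` rows from
#'   [specific_adsorbed_mass()] at the same evaluation volume.
#' @param flux_tol Relative flux-matching tolerance (default 0.15).
#' @return One-row tibble of class `adsorption_result` with additional
#'   column `significant` (TRUE when q > 2 sigma).
#' @export
subtract_support <- function(q_total, q_support, flux_tol = 0.15) {
  stopifnot(inherits(q_total, "adsorption_result"),
            inherits(q_support, "adsorption_result"))
  if (abs(q_total$evaluation_volume - q_support$evaluation_volume) >
      1e-9 * q_total$evaluation_volume) {
    abort("Evaluation volumes must match for support subtraction.",
          class = "poreforce_domain_error")
  }
  ft <- q_total$flux; fs <- q_support$flux
  if (is.finite(ft) && is.finite(fs) && ft > 0 &&
      abs(ft - fs) > flux_tol * ft) {
    abort(sprintf("Fluxes differ by more than %.0f%% (%.3g vs %.3g L m-2 h-1).",
                  100 * flux_tol, ft, fs),
          class = "poreforce_domain_error")
  }
  q <- q_total$q_ads_A - q_support$q_ads_A
  sig <- sqrt(q_total$sigma^2 + q_support$sigma^2)
  out <- tibble(
    label = paste0(q_total$label, " - ", q_support$label),
    flux = q_total$flux,
    q_ads_A = q,
    sigma = sig,
    evaluation_volume = q_total$evaluation_volume,
    censored_fraction = max(q_total$censored_fraction,
                            q_support$censored_fraction),
    n_samples = q_total$n_samples,
    membrane_area = q_total$membrane_area,
    significant = q > 2 * sig
  )
  if (q <= sig) {
    attr(out, "note") <- "insignificant (within 1 sigma of zero)"
  }
  class(out) <- c("adsorption_result", class(out))
  out
}

#' Saturation plateau of a breakthrough curve
#'
#' Averages the tail of the curve and classifies the end state:
#' `full-breakthrough` when the plateau reaches c/c0 >= 0.95; `retention`
#' when the tail is flat below 0.95 (steady-state rejection, retention =
#' 1 - plateau); `unsaturated` when the tail is still rising.
#'
#' @param curve A [breakthrough_curve()].
#' @param tail_fraction Fraction of samples treated as the tail (default
#'   0.2, at least 3 samples).
#' @param flat_rise Maximum fitted c/c0 rise across the tail still counted
#'   as flat (default 0.05).
#' @return One-row tibble: `plateau`, `retention`, `classification`,
#'   `tail_slope` (per mL), `n_tail`.
#' @export
saturation_plateau <- function(curve, tail_fraction = 0.2, flat_rise = 0.05) {
  stopifnot(inherits(curve, "breakthrough_curve"))
  n <- nrow(curve)
  n_tail <- max(3L, ceiling(tail_fraction * n))
  if (n < n_tail) {
    abort(sprintf("Need at least %d samples for the tail estimate.", n_tail),
          class = "poreforce_domain_error")
  }
  tl <- tail(as_tibble(curve), n_tail)
  plateau <- mean(tl$c_over_c0)
  slope <- unname(coef(lm(c_over_c0 ~ volume_mL, data = tl))[2])
  rise <- slope * (max(tl$volume_mL) - min(tl$volume_mL))
  classification <- if (plateau >= 0.95) {
    "full-breakthrough"
  } else if (abs(rise) <= flat_rise) {
    "retention"
  } else {
    "unsaturated"
  }
  tibble(
    plateau = plateau,
    retention = ifelse(classification == "retention", 1 - plateau, NA_real_),
    classification = classification,
    tail_slope = slope,
    n_tail = n_tail
  )
}

#' Join adsorption results with the force model
#'
#' Produces the flux - velocity - drag force - adsorbed mass table that
#' links breakthrough measurements to the force framework: one row per
#' flux with the in-pore velocity, drag force, predicted regime and the
#' measured adsorbed mass with its significance (q > 2 sigma).
#'
#' @param results A data frame of adsorption results (rows from
#'   [specific_adsorbed_mass()] or [subtract_support()], bindable), or a
#'   list of them.
#' @param membrane A [membrane_spec()].
#' @param solute A [solute_spec()].
#' @param fluid A [fluid_state()].
#' @param model A [threshold_model()].
#' @return Tibble ordered by flux: `flux`, `velocity`, `f_drag`,
#'   `f_drag_pN`, `q_ads_A`, `sigma`, `significant`, `regime`.
#' @export
regime_table <- function(results, membrane, solute,
                         fluid = fluid_state(),
                         model = threshold_model(fluid = fluid)) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- dplyr::bind_rows(results)
  }
  if (nrow(results) < 1) {
    abort("Need at least one adsorption result.", class = "poreforce_domain_error")
  }
  if (!all(c("flux", "q_ads_A", "sigma") %in% names(results))) {
    abort("`results` must have columns flux, q_ads_A, sigma.",
          class = "poreforce_domain_error")
  }
  f_f <- friction_threshold(solute, model)
  results |>
    dplyr::mutate(
      velocity = flux_to_pore_velocity(.data$flux, membrane),
      f_drag = drag_force(.data$velocity, solute, fluid),
      f_drag_pN = .data$f_drag * 1e12,
      significant = .data$q_ads_A > 2 * .data$sigma,
      regime = classify_regime(.data$f_drag, f_f)
    ) |>
    dplyr::select(dplyr::any_of(c(
      "label", "flux", "velocity", "f_drag", "f_drag_pN",
      "q_ads_A", "sigma", "significant", "regime"
    ))) |>
    dplyr::arrange(.data$flux)
}
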