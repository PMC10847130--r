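# Shared fixtures built in code.

fx_membrane <- function(...) {
  args <- modifyList(
    list(name = "vacnt_1p7", pore_diameter = 1.7e-9, thickness = 50e-6,
         porosity = 0.034, tortuosity = 1.2),
    list(...)
  )
  do.call(membrane_spec, args)
}

fx_e2 <- function(...) {
  args <- modifyList(
    list(name = "E2", molecular_weight = 272.4,
         hydrodynamic_diameter = 0.8e-9),
    list(...)
  )
  do.call(solute_spec, args)
}

# The four steroid hormones with plausible configured diameters obeying
# d(E1) < d(E2) < d(T) < d(P); E2's is the built-in 0.8 nm.
fx_hormones <- function(hamaker = 2.8e-20) {
  list(
    E1 = solute_spec("E1", 270.4, 0.76e-9, hamaker_constant = hamaker),
    E2 = solute_spec("E2", 272.4, 0.80e-9, hamaker_constant = hamaker),
    T  = solute_spec("T",  288.4, 0.84e-9, hamaker_constant = hamaker),
    P  = solute_spec("P",  314.5, 0.90e-9, hamaker_constant = hamaker)
  )
}

# Piecewise-linear breakthrough curve: trapezoid integration is exact here.
# Detection-limit flooring is disabled so the closed-form oracle applies
# even at c = 0; censoring behaviour is tested separately.
fx_curve <- function(volume, rel, c0 = 100, area = 2, flux = 27,
                     label = "fixture", detection_limit = 0) {
  breakthrough_curve(
    data.frame(volume_mL = volume, c_over_c0 = rel),
    feed_concentration = c0, membrane_area = area, flux = flux, label = label,
    detection_limit = detection_limit
  )
}

# Closed-form area under (c0 - c) for a piecewise-linear relative curve,
# the independent oracle for the trapezoid quadrature (ng cm^-2).
fx_pwl_mass <- function(volume, rel, c0 = 100, area = 2) {
  d <- (c0 / 1000) * (1 - rel)
  sum(diff(volume) * (head(d, -1) + tail(d, -1)) / 2) / area
}
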