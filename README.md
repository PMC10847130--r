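# poreforce

Force-interplay modelling of steroid-hormone micropollutant transport and
adsorption in slippery nanopores.

## The problem

Vertically aligned carbon-nanotube (VaCNT) membranes conduct water through
atomically smooth, hydrophobic nanopores (1.7–3.3 nm diameter) with large
wall slip, so flow inside the pores is plug-like: even a molecule sitting
against the wall feels nearly the full water velocity. Whether a trace
hormone molecule (estrone, 17β-estradiol, testosterone, progesterone at
~100 ng L⁻¹) adsorbs in such a pore or is swept through is decided by four
forces:

- hydrodynamic drag along the flow, `F_H = 3πμ·d_SH·v`;
- sphere–wall van der Waals adhesion, `F_A = H·d_SH³ / (16·g⁴)`;
- short-range electron-cloud repulsion `F_R`, balancing `F_A` at a contact
  gap of ≈0.3 nm;
- wall friction `F_F`, modelled as Amontons-style proportional to the
  contact adhesion and calibrated to the observed adsorption threshold.

The solute is classified **adsorptive** when `F_H < F_F` and in
**advective clearance** otherwise; because drag is linear in flux the
transition is a single threshold flux (≈37 L m⁻² h⁻¹ for 17β-estradiol on
the 1.7 nm membrane with package defaults).

The package is aimed at membrane and water-treatment researchers analysing
micropollutant breakthrough in nanoporous membranes. It implements:

- slip-corrected Hagen–Poiseuille pore hydraulics, enhancement-factor and
  slip-length inversion, permeability bookkeeping, Péclet/residence/
  diffusion timescales (`flow_solution()`, `timescale_report()`);
- the four-force profile and regime classifier (`force_profile()`,
  `threshold_model()`, `regime_transition_flux()`, `rank_by_adhesion()`);
- breakthrough-curve mass balance: specific adsorbed mass by trapezoid
  quadrature with uncertainty propagation, detection-limit censoring,
  support-membrane subtraction, plateau classification
  (`specific_adsorbed_mass()`, `subtract_support()`, `regime_table()`);
- a seeded synthetic breakthrough generator with closed-form ground truth
  for end-to-end validation (`synthetic_config()`,
  `generate_experiment_set()`, `parameter_recovery_report()`).

Everything is data-frame first: curves, profiles and reports are tibbles,
with `tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## Worked example

```r
library(poreforce)

m  <- default_membranes()$vacnt_1p7   # 1.7 nm pores, 3.4% porosity
e2 <- default_solutes()$E2            # 17β-estradiol, d = 0.8 nm

prof <- force_profile(m, e2, c(6, 15, 30, 38, 57))
subset(tidy(prof), force == "drag",
       select = c(flux, velocity, piconewtons, regime))
#>   flux velocity piconewtons              regime
#> 1    6 0.000049    0.000345          adsorptive
#> 2   15 0.000123    0.000864          adsorptive
#> 3   30 0.000245    0.001727          adsorptive
#> 4   38 0.000310    0.002188 advective-clearance
#> 5   57 0.000466    0.003282 advective-clearance

regime_transition_flux(m, e2)   # L m^-2 h^-1
#> [1] 36.7
adhesive_force(e2) * 1e12       # contact adhesion, pN
#> [1] 110.6
```

The drag force grows from 3.5×10⁻⁴ to 3.3×10⁻³ pN across the 6–57
L m⁻² h⁻¹ sweep, crossing the calibrated friction threshold
(2.1×10⁻³ pN) between 30 and 38 L m⁻² h⁻¹ — below the transition the
hormone appears adsorbed, above it it is cleared. The constant 110.6 pN
wall adhesion is five orders of magnitude stronger than the drag, which is
why the molecule rides along the wall at its 0.3 nm equilibrium gap rather
than escaping radially.

End-to-end breakthrough analysis on a synthetic experiment with known
truth:

```r
cfg <- synthetic_config(seed = 1L)        # flux sweep 6..57, 5% noise
set <- generate_experiment_set(cfg)
q <- subtract_support(
  specific_adsorbed_mass(set$curve_total[[1]]),
  specific_adsorbed_mass(set$curve_support[[1]])
)
q[, c("flux", "q_ads_A", "sigma", "significant")]
#>   flux q_ads_A  sigma significant
#> 1    6    0.91 0.0812        TRUE
set$truth_membrane[1]
#> [1] 0.831
```

The recovered specific adsorbed mass (0.91 ± 0.08 ng cm⁻²) agrees with
the generator's closed-form ground truth (0.83 ng cm⁻²) within one
standard deviation of the 5% analytical noise.

See the methods vignette (`vignettes/force-interplay.Rmd`) for the model's
assumptions, calibration choices and limitations.

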