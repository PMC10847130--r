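# Example configuration: the four steroid hormones with user-supplied
# hydrodynamic diameters (only E2's diameter is a package default; the
# others must be configured and obey d(E1) < d(E2) < d(T) < d(P)).
# All values in SI units.
fluid:
  temperature: 296.15          # K (23 degC filtration temperature)
solute:
  E1:
    molecular_weight: 270.4    # g/mol, estrone
    hydrodynamic_diameter: 0.76e-9
  E2:
    molecular_weight: 272.4    # g/mol, 17beta-estradiol
    hydrodynamic_diameter: 0.80e-9
  T:
    molecular_weight: 288.4    # g/mol, testosterone
    hydrodynamic_diameter: 0.84e-9
  P:
    molecular_weight: 314.5    # g/mol, progesterone
    hydrodynamic_diameter: 0.90e-9
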