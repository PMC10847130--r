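# c0_ng_per_L: 100
# area_cm2: 2
# flux_lmh: 27
# label: synthetic_total_flux27
# detection_limit_ng_L: 0.2
volume_mL,c_over_c0,c_ngL,below_detection
0,0.58636149322922,58.636149322922,FALSE
6.66666666666667,0.716259146643749,71.6259146643749,FALSE
13.3333333333333,0.751490534888587,75.1490534888587,FALSE
20,0.882008776046421,88.2008776046421,FALSE
26.6666666666667,0.842629541177705,84.2629541177705,FALSE
33.3333333333333,0.890515756106437,89.0515756106437,FALSE
40,0.976277869097928,97.6277869097928,FALSE
46.6666666666667,0.90656781758056,90.656781758056,FALSE
53.3333333333333,0.890042924331402,89.0042924331402,FALSE
60,1.03519902732883,103.519902732883,FALSE
66.6666666666667,0.977600289740241,97.7600289740241,FALSE
73.3333333333333,0.974873310023546,97.4873310023546,FALSE
80,1.01661479409837,101.661479409837,FALSE
86.6666666666667,1.05577044633277,105.577044633277,FALSE
93.3333333333333,0.992205730877583,99.2205730877583,FALSE
100,1.05862290614615,105.862290614615,FALSE
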