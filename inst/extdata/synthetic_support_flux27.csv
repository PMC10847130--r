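# c0_ng_per_L: 100
# area_cm2: 2
# flux_lmh: 27
# label: synthetic_support_flux27
# detection_limit_ng_L: 0.2
volume_mL,c_over_c0,c_ngL,below_detection
0,0.890293606121209,89.0293606121209,FALSE
6.66666666666667,0.863512882257354,86.3512882257354,FALSE
13.3333333333333,0.875322179603527,87.5322179603527,FALSE
20,1.00260018711806,100.260018711806,FALSE
26.6666666666667,0.888024557434605,88.8024557434605,FALSE
33.3333333333333,1.00960504138441,100.960504138441,FALSE
40,0.908121647506957,90.8121647506957,FALSE
46.6666666666667,0.999757703256072,99.9757703256072,FALSE
53.3333333333333,1.02320720424704,102.320720424704,FALSE
60,0.870487521364139,87.0487521364139,FALSE
66.6666666666667,1.01925886666504,101.925886666504,FALSE
73.3333333333333,0.951908438753695,95.1908438753695,FALSE
80,0.940567792393355,94.0567792393355,FALSE
86.6666666666667,1.01720390595001,101.720390595001,FALSE
93.3333333333333,1.00994925173999,100.994925173999,FALSE
100,0.925973409696121,92.5973409696121,FALSE
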