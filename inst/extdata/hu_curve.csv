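# piecewise-linear HU <-> linear attenuation calibration at 140 keV
# nodes: air, lung, adipose, water, muscle, trabecular bone, cortical bone
# units: mu_cm = 1/cm
# version: 1 (synthetic default nodes; swappable)
hu,mu_cm
-1000,0.000186
-700,0.0465
-98,0.1488
0,0.1537
40,0.1585
300,0.178
1500,0.27
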