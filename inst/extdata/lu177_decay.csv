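# nuclide: Lu-177 (daughter Hf-177, Z=72, A=177)
# units: energy_kev = keV (endpoint for beta branches); yield = emissions per decay
# source: evaluated decay-scheme compilation (ICRP-107-style); CE yields from
#   internal conversion coefficients of the 112.95/208.37 keV transitions
# version: 1
kind,energy_kev,yield,shape
beta_branch,498.3,0.789,allowed
beta_branch,385.3,0.09,allowed
beta_branch,176.5,0.121,allowed
conversion_electron,47.6,0.103,
conversion_electron,102.3,0.037,
conversion_electron,110.4,0.0093,
conversion_electron,143,0.012,
conversion_electron,197.7,0.0027,
conversion_electron,205.8,7e-04,
auger,7.3,0.1,
auger,47,0.01,
gamma,208.37,0.1038,
gamma,112.95,0.0617,
gamma,321.32,0.00216,
gamma,249.67,0.00205,
gamma,71.64,0.00154,
xray,55.8,0.068,
xray,63.2,0.017,
xray,7.9,0.15,
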