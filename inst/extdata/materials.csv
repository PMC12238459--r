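# units: density = g/cm^3; stopping_power_scale, compton_scale = ratio to water
# zeff = effective atomic number used for the photoelectric cross-section scaling
# version: 1
name,density,stopping_power_scale,compton_scale,zeff
air,0.0012,0.975,0.899,7.64
water,1,1,1,7.42
soft_tissue,1,0.991,0.997,7.46
tumour,1,0.991,0.997,7.46
bone,1.55,0.921,0.927,13.8
marrow,1.03,0.989,0.992,7.1
lung,0.3,0.991,0.997,7.46
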