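# published tumour self-dose S-values for unit-density spheres in the left
# shoulder, Gy/(MBq s), with OLINDA 25 g sphere-model reference values
# resolution: hr = 0.29 mm voxels (expanded 140x140x355), lr = 0.625 mm (80x80x175)
# version: 1
mass_g,resolution,s_olinda,s_ref,diff_pct
0.12,hr,1.83E-04,1.82E-04,-0.69
0.13,lr,1.66E-04,1.64E-04,-1.10
0.22,hr,9.51E-05,9.51E-05,-0.01
0.26,lr,8.33E-05,8.30E-05,-0.29
0.33,hr,6.42E-05,6.44E-05,0.26
0.37,lr,5.76E-05,5.76E-05,0.02
0.44,hr,4.88E-05,4.90E-05,0.38
0.48,lr,4.43E-05,4.44E-05,0.18
0.54,hr,3.95E-05,3.97E-05,0.46
0.60,lr,3.58E-05,3.59E-05,0.27
0.65,hr,3.31E-05,3.33E-05,0.51
0.71,lr,3.02E-05,3.03E-05,0.33
0.75,hr,2.86E-05,2.87E-05,0.54
0.81,lr,2.64E-05,2.65E-05,0.35
0.86,hr,2.51E-05,2.52E-05,0.56
0.93,lr,2.31E-05,2.32E-05,0.39
0.96,hr,2.24E-05,2.25E-05,0.57
1.04,lr,2.07E-05,2.08E-05,0.39
1.07,hr,2.02E-05,2.03E-05,0.57
1.15,lr,1.88E-05,1.89E-05,0.42
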