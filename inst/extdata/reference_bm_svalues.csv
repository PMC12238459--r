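# published bone-marrow-targeted S-values, Gy/(Bq s), compared between an
# independent reference phantom study and the LR/HR voxel phantoms; kept
# verbatim with provenance (these are comparison data, not reproduced here)
# note: the BM self-dose LR value differs between published tables
#   (1.16E-11 in this comparison table vs 1.57E-11 in the full LR table);
#   both provenances are retained, unreconciled
# version: 1
source_organ,s_reference_study,s_lr,lr_diff_pct,s_hr,hr_diff_pct,provenance
Liver,1.11E-14,1.66E-14,49.7,3.16E-15,-71.6,comparison_table
Kidneys,3.52E-15,3.74E-15,6.2,1.93E-15,-45.1,comparison_table
Spleen,1.53E-14,1.43E-14,-6.6,5.92E-15,-61.4,comparison_table
BM,8.40E-11,1.16E-11,-86.2,1.07E-11,-87.3,comparison_table
BM,,1.57E-11,,,,full_lr_table
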