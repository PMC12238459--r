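Package: voxeldose
Title: Voxel-Phantom Dosimetry and S-Values for Lu-177 Preclinical Studies
Version: 0.1.0
Authors@R:
    person("Voxeldose", "Developers", email = "voxeldose@example.org",
           role = c("aut", "cre"))
Description: Synthetic voxelized rodent-like phantoms with subcutaneous
    shoulder tumour xenografts, a simplified Monte Carlo voxel dose engine
    for Lu-177 beta and photon emissions, and the MIRD-schema S-value
    pipeline used in preclinical bone-marrow dosimetry: batch merging,
    history-by-history style dose uncertainty, S-value tables with
    propagated uncertainties, organ-mass corrections against reference
    phantoms, and tumour-size sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
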