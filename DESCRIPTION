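Package: ecbspill
Title: Spill-In from Extra-Cerebral Off-Target Binding in Tau PET
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the effect of extra-cerebral off-target binding (ECB)
    in the meninges and sinus on tau PET quantification with digital brain
    phantoms and a resolution-matched forward model. Builds parametric
    phantoms with the spill-relevant adjacencies (sinus/entorhinal cortex,
    meningeal shell/inferior cerebellar reference region), assembles binned
    ECB emission maps calibrated to target SUVRs, simulates noiseless and
    Poisson-noise PET images at scanner resolution, computes SUV/SUVR and
    ROI statistics, derives and applies linear simulation-based spill-in
    correction factors, performs Mueller-Gartner partial-volume correction,
    searches the tau-detection threshold on input activity, and stratifies
    scans into ECB tiers by ROC/Youden analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
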