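Package: collateraltime
Title: Time-Resolved Collateral Ratio Analysis for CT Perfusion and
    Multiphase CTA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frame-by-frame automated collateral scoring for dynamic CT
    perfusion (CTP) and multiphase CT angiography (mCTA) in intracranial
    large-vessel occlusion. Computes the collateral ratio (CR, the
    occluded-to-contralateral enhanced vessel volume ratio) per frame,
    builds arterial and venous time-intensity curves, classifies contrast
    acquisition phases on a normalized arteriovenous enhancement-ratio
    curve, temporally aligns sparse mCTA acquisitions to the dense CTP
    time axis by matching AV ratios, extracts CRs at predefined landmark
    time points, and runs cohort association statistics. Ships a seeded
    contrast-enhancement phantom generator so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
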