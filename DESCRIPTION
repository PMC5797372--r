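Package: abqsp
Title: Quantitative Systems Pharmacology of Amyloid-Beta Effects on Cognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of how low-order amyloid-beta (Abeta40,
    Abeta42) aggregate load modulates glutamatergic (NMDA) and nicotinic
    (alpha7) neurotransmission, and of the downstream consequences for
    ADAS-Cog cognitive outcomes in virtual Alzheimer's disease and MCI
    populations. Provides the isoform-specific coupling equations and the
    17x17 load-effect matrix, amyloid deposition pharmacodynamics with
    APOE-dependent rates and therapeutic reductions (BACE inhibition,
    gamma-secretase inhibition, solanezumab), a mass-conserving quadrature
    scheme for fractional loads, a calibrated reduced-form cognitive
    surrogate with logistic network-reserve links, competitive
    scopolamine/acetylcholine receptor pharmacology at muscarinic M1/M2
    receptors, a virtual-trial engine with SUVR calibration and APOE
    trajectory analysis, a parameter-grid sensitivity scan over three
    clinical constraint conditions, and seeded synthetic patient cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
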