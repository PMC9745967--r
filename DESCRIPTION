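Package: glucanSim
Title: Mechanistic Simulation of 1,3-beta-Glucan Remodelling Enzymes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discrete mechanistic models of fungal 1,3-beta-glucan metabolism:
    a rooted-tree representation of linear and 1,6-branched gluco-oligosaccharides
    with canonical parsing and serialization, an exo-1,3-beta-glucanase digestion
    engine with run-length stopping rules, a 1,3-beta-transglucanase
    (cleave-and-transfer) engine producing 1,6-branched hybrid oligomers and the
    +DP3 product series, MALDI [M+Na]+ mass prediction and arithmetic-series
    detection for peak lists, stoichiometric accounting (microgram/nanomole
    conversions, difference formulas, molar ratios, enzyme-unit arithmetic), and
    seeded synthetic-data generators for substrate pools, laminarin-like polymer
    ensembles, quantification tables and peak lists.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Metabolomics, MassSpectrometry, Software
RoxygenNote: 7.3.3
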