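Package: prospr
Title: Gene-Specific Missense Variant Pathogenicity Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Per-gene (protein-specific) interpretation of missense variants.
    Annotates variants with sequence- and structure-derived features
    (evolutionary conservation grade, Richards-scale residue volume change,
    hydrophobicity and charge transitions, side-chain relative solvent
    accessibility by the Shrake-Rupley method with Naccess-style
    normalisation, secondary structure, disorder, stability and interaction
    effect tracks, 3D variant clustering), trains gene-specific binary
    classifiers (Hoeffding tree, LogitBoost over decision stumps, simple
    logistic) after supervised class balancing and entropy/MDL
    discretisation, selects the best algorithm and a minimal feature subset
    by repeated stratified cross-validation on the Matthews correlation
    coefficient, and optimises gene-specific pathogenicity thresholds for
    external predictor scores over a 21-point grid with repeated five-fold
    cross-validation.  Includes a deterministic synthetic-data generator
    (toy protein structures, class-conditional variant cohorts and
    Beta-distributed predictor scores) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    jsonlite,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
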