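Package: hergdb
Title: Integration and Consensus Classification of hERG Bioactivity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes heterogeneous hERG potassium-channel bioactivity
    records from multiple sources (literature, patent, phenotypic and
    high-throughput screening collections), standardizes and merges chemical
    structures by canonical parent, and classifies compounds into hERG
    inhibitors, inactives and inconclusives by a step-wise consensus
    procedure (unanimity, 10-fold outlier elimination, two-thirds majority,
    IC50 priority over single-concentration data, and stricter thresholds
    for HTS sources). Characterizes the integrated set by Murcko-framework
    scaffold diversity, chemical-space coverage, physicochemical profiles
    and binding versus patch-clamp assay concordance, and ships a synthetic
    multi-source data generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel (obabel on PATH)
Config/testthat/edition: 3
biocViews: Cheminformatics, DataImport, Classification
RoxygenNote: 7.3.3
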