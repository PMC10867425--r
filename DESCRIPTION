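Package: civaR
Title: Predicting and Stratifying Chromosomal-Instability-Aiding Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage toolkit for studying naturally occurring
    loss-of-function variants in chromosome segregation genes. Stage one
    screens variant tables collated from population databases: HGVS
    protein-consequence parsing, loss-of-function classification, a
    prevalence filter for chromosomal-instability-aiding variant (CIVa)
    candidates, cross-database merging, allele frequencies, and lollipop
    and JSON database exports. Stage two predicts truncated or
    alternative-start protein isoforms by scanning coding sequences for
    downstream Kozak-consensus initiation sites and reports retained and
    removed protein features and predicted fusion masses. Stage three
    quantifies the cellular impact of a variant from two-channel
    fluorescence time-lapse imaging: kinetochore particle detection in a
    centromere-marker channel, kinetochore/cytoplasm intensity ratios in
    the measurement channel, particle linking, sister-kinetochore pairing,
    inter-centromere stretch with unstretched-state normalization, and
    mitotic timing statistics (cumulative frequency, t50, per-replicate
    event fractions, standard hypothesis tests). Seeded synthetic-data
    generators with full ground truth make every stage testable without
    access to microscopes or restricted cohort databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    multcomp,
    stats,
    utils,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
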