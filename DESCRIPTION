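Package: consortr
Title: Consortship Stability Analysis from Scan and Focal Sampling of
    Japanese Macaques
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse female-female consortship stability in
    Japanese macaques (Macaca fuscata) from raw behavioural observation
    logs. Reads scan-sampling sighting logs, focal-sampling event logs and
    a population roster; segments pair sightings into consort bouts under
    a three-day gap rule; validates 20-minute focal sessions against the
    observation protocol; computes pair-level behavioural indices
    (mounting frequency, pelvic-movement rate, mounting reciprocity,
    intensive body contact and grooming rates, pair consort duration); and
    reproduces the study-level statistics (Spearman correlation matrix
    with Holm-Bonferroni correction, Kruskal-Wallis and Mann-Whitney group
    comparisons, demographic summaries). A seeded synthetic season
    generator with known ground truth makes every pipeline stage testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
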