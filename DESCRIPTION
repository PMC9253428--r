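Package: nccclaims
Title: Nested Case-Control Drug-Safety Analysis of Prescription Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pharmacovigilance studies that ascertain suspected
    adverse-reaction cases from longitudinal prescription-claims records using
    marker-drug surrogates, match controls by propensity score with a greedy
    1:1 algorithm, and estimate crude, discordant-pair and multivariable
    conditional-logistic odds ratios for concomitant medications. Includes a
    seeded synthetic-claims generator with known ground truth so the whole
    pipeline can be validated end to end, plus run manifests and attrition
    flowcharts for reproducible reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    tools
Suggests:
    survival,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
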