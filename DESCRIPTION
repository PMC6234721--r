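Package: valbench
Title: Benchmarking Germline Variant Calling Against Sanger-Validated Truth Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates germline variant-calling pipelines against a truth
    catalog of orthogonally (Sanger) validated positive and negative sites.
    Reads per-sample VCF callsets (plain, multi-sample or gVCF), normalizes
    variant representations to their minimal form, scores every truth site for
    detection and representation accuracy (exact-position matching for base
    substitutions, windowed counting with exact-match representation checks
    for indels), and aggregates site verdicts into sensitivity, specificity
    and false-detection-rate summaries. Also provides baseline (Group A/B)
    benchmarking against reference pipelines, site-level regression comparison
    between caller versions, QUAL-threshold filter sweeps, tabular and
    one-page report outputs, and a seeded synthetic scenario generator with a
    fully known planted-outcome ledger for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
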