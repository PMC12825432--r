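Package: icscreen
Title: Multi-Round Screening for Novel Inhibitory Immune Checkpoints and
    Their Ligands
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a multi-round transcriptomic screening pipeline that
    nominates candidate inhibitory immune checkpoints from regulatory T cell
    (Treg) and FoxP3-upregulated plasma-membrane gene sets, filters them by
    down-regulation calls across knockout differential-expression datasets,
    classifies knockout targets into high and low regulatory hierarchy by
    their effect on a reference checkpoint panel, applies a k-of-n stringency
    filter, and triages candidate ligands through plasma-membrane,
    antigen-presenting-cell marker, and tolerogenic-subset filters. Ships a
    seeded synthetic-data generator that plants the full screening structure
    for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
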