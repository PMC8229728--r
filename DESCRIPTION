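Package: basidioSI
Title: Somatic Incompatibility Genetics and Reader/Writer Dynamics in
    Basidiomycete Fungi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models somatic incompatibility (SI) in basidiomycete fungi.
    Provides exact, closed-form and Monte-Carlo calculations of the
    fraction of heterokaryon pairs that are somatically compatible at
    multi-allelic incompatibility loci, including sibling cohorts from a
    single fruiting body and pairwise population surveys used to delimit
    fungal individuals; a mass-action kinetic model of a reader/writer
    post-translational-modification nonself-recognition system with a
    threshold-triggered cell-death signal, contrasting cytoplasmic mixing
    with fertilization by nuclear migration; and a lifecycle scenario
    engine that scores candidate recognition mechanisms against the
    canonical basidiomycete matings, modelling the race between nuclear
    migration and fusion-cell death.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
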