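Package: methpath
Title: Pathway Projection and Visualization of DNA Methylation and Gene
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects per-CpG DNA methylation (beta values) and gene
    expression (FPKM) matrices onto KEGG pathway graphs parsed from KGML.
    Provides site-level filters (standard deviation, beta range, genomic
    location, explicit site lists), per-gene and per-group aggregation,
    Euclidean similar-pattern mining, methylation-expression Spearman
    correlation screening, sample ordering for playback, and deterministic
    color-coded SVG rendering of pathway, grid and playback views, plus a
    probe-to-gene annotation converter, a synthetic two-group data
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
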