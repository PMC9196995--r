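Package: bloomfinish
Title: Alignment-Free Genome Assembly Polishing and Gap Filling with
    k-mer Bloom Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Finishes draft long-read genome assemblies using accurate
    short reads, without read alignment. Short-read k-mers with
    multiplicity of two or more are stored in two-level cascading Bloom
    filters; a long-to-short k-mer sweep corrects substitutions and
    small indels (up to 5 nt) in the draft and soft-masks stretches it
    cannot fix; short unmasked islands between masked runs are
    consolidated; and both N-gaps and soft-masked regions are then
    filled by bounded depth-first traversal of the implicit de Bruijn
    graph defined by the Bloom filter. Includes a Bloom filter sizing
    calculator based on exact k-mer cardinality counting, and a
    synthetic genome/read simulator with a truth-based evaluator for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    methods,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
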