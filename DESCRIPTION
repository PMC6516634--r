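Package: cenisland
Title: Discovery of Centromere Islands from CENP-A ChIP-seq, Hi-C and
    Chromatin-Fiber Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for locating candidate centromeres in
    repeat-rich genome assemblies from CENP-A chromatin
    immunoprecipitation sequencing.  Four complementary enrichment
    analyses are provided: tandem k-mer (satellite) enrichment in raw
    reads, read assignment to a consensus repeat library with a
    top-percentile rule and per-position consensus profiles, de novo
    assembly of ChIP reads into contigs (ChIPtigs) with post hoc
    enrichment and projection onto the assembly, and Poisson
    local-background peak calling with strand cross-correlation quality
    metrics and replicate-reproducibility filtering.  Islands of complex
    DNA flanked by satellite arrays are detected and ranked into
    candidate centromeres.  Supporting modules quantify Hi-C contacts
    between genome categories with a Kruskal-Wallis/Dunn plus Wilcoxon
    consensus rule, calibrate chromatin-fiber FISH measurements
    (kb per micrometre) and size CENP-A domains, evaluate ChIP-qPCR
    fold enrichment and 2^-dCt expression, and design repeat-tolerant
    oligo FISH probes with a melting-temperature window and a genomic
    18-mer occurrence filter.  A seeded synthetic-data generator plants
    centromere islands with known ground truth so that every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr,
    optparse
Config/testthat/edition: 3
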