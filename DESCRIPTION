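Package: skewatlas
Title: Genome Atlases and Signal Analysis of Nucleotide-Skew Properties
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes sliding-window genomic properties (GC skew, AT skew,
    keto skew, GC content) and their cumulative forms along prokaryotic
    chromosomes, locates the extrema of cumulative skews as candidate
    replication origin and terminus positions, condenses property tracks to
    dyadic vectors and analyses them with a maximal-overlap discrete wavelet
    transform (Haar, D4, LA8 and FK4 filters), autocorrelation and
    cross-correlation with normal-approximation confidence bounds, and
    renders feature and property tracks as linear or circular genome-atlas
    SVG documents with legends, static track transforms, caterpillar track
    duplication and scale-independent layout.  Includes a synthetic-genome
    generator with programmable skew polarity so the whole pipeline is
    testable without downloads, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    Biostrings,
    xml2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
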