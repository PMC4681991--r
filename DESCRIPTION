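Package: rnfr
Title: Read Naming Format Tools for Simulated Reads and Mapper Evaluation
Version: 0.1.0
Authors@R:
    person("rnfr", "developers", email = "rnfr@example.org", role = c("aut", "cre"))
Description: Implements the Read Naming Format (RNF), a convention for
    encoding the true genomic origin of simulated sequencing reads in
    their read names. Provides an encoder/decoder and validator for RNF
    names, converters from the naming dialects of popular read
    simulators (wgsim, dwgsim, CuReSim) and from SAM truth files, a
    minimal built-in read simulator and sample mixer for contamination
    experiments, LiftOver chain-file transformation of RNF coordinates,
    and a mapping-quality-parametrized evaluation engine that classifies
    alignments against their encoded truth and produces
    sensitivity/precision/FDR curves with TSV, SVG and static HTML
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    S4Vectors,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments,
    rtracklayer,
    GenomicRanges,
    IRanges,
    xml2,
    jsonlite
Config/testthat/edition: 3
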