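Package: svkit
Title: Somatic Structural Variant Calling with Single Breakends and SV Phasing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale somatic structural variant calling toolkit for paired
    tumour/normal short-read data. Extracts split-read, soft-clip, indel,
    discordant-pair and unmapped-mate evidence from SAM alignments, assembles
    breakend contigs with a positional de Bruijn graph, realigns contigs into
    split-alignment chains, and performs probabilistic breakpoint and single
    breakend calling via two-pass maximal-clique clustering. Calls are annotated
    with exact and inexact breakpoint microhomology, a full per-sample support
    breakdown, assembly-based cis/trans phase links and transitive call
    collapsing, then classified by an enumerated somatic filter with optional
    panel-of-normals. Includes a deterministic tumour/normal read simulator with
    repeat-array single-breakend cases and truth-set evaluation, and
    copy-number-consistency estimators of false negative and false discovery
    rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    Biostrings,
    IRanges,
    Rsamtools,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
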