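Package: aedscreen
Title: Sort-Seq Discovery of Signalling-Decoupled TCR Variants
Version: 0.1.0
Authors@R:
    person("AED Screen", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for engineering T-cell receptor (TCR) variants
    whose antigen binding is decoupled from CD3-mediated signalling. Provides
    conserved-motif discovery in TCR germline genes via progressive multiple
    sequence alignment and per-column conservation profiling, degenerate-codon
    (NNK) saturation-mutagenesis library design with exact diversity
    accounting, a synthetic three-round FACS sort-seq screen simulator with
    amplicon read emission, anchored read parsing with the variation-only
    cleaning rule, frequency/rank trajectory tracking, decoupling-candidate
    calling, and radial-intensity quantification of T-cell rings around
    tumour-cell clusters with one-way ANOVA group comparison. A command-line
    entry point orchestrates the stages deterministically.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    digest,
    jsonlite,
    methods,
    png,
    S4Vectors,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
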