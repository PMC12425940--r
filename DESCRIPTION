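Package: cubana
Title: Codon Usage Bias Analysis for Gene-Family Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the standard battery of codon usage bias (CUB) statistics
    for a set of coding sequences: nucleotide composition indices (GC, GC1-3,
    GC12, GC3s, A3s/T3s/G3s/C3s in the CodonW dialect), relative synonymous
    codon usage (RSCU, per gene and pooled), Wright's effective number of
    codons (ENC), and the classical mutation-versus-selection diagnostics
    (ENC-plot against the expected curve, Sueoka PR2 bias plot over four-fold
    degenerate families, neutrality regression of GC12 on GC3, and the index
    correlation matrix). Includes principal component analysis of the 56-codon
    RSCU matrix, optimal codon identification by the delta-RSCU extreme-group
    method, a seeded synthetic CDS generator with controllable mutational GC3
    pressure and translational selection strength, and a pipeline that emits
    the full table bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
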