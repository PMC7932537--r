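Package: selectome
Title: Quantitative Protease Specificity Profiling from Substrate Phage
    Display Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Profiles the substrate specificity of proteases from deep
    sequencing of substrate phage display selections. Hexapeptide substrates
    are extracted from amplicon reads by six-frame translation and
    flank-anchored insert matching, grouped into P3-P1' tetramer clusters
    (with redundancy elimination for selected sets), and scored by the
    relative probability (RP) of each tetramer in the selection versus the
    naive library. Shannon entropy and Kullback-Leibler divergence between
    the tetramer distributions quantify specificity, and the RP value at
    which the cumulative divergence crosses zero defines the "selectome",
    the set of tetramer recognition motifs that, as a whole, is the
    quantitative specificity signature of the enzyme. Additional tools
    validate RP against measured catalytic efficiency constants, build
    positional frequency profiles across the P5-P3' window, annotate and
    classify cleavage sites in proteins (from N-terminomics peptides or
    P4-P4' octamer records), and simulate the whole selection experiment
    under pseudo-first-order cleavage kinetics so the pipeline is testable
    end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
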