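Package: crisprVA
Title: Characterization Toolkit for Type V-A CRISPR Nucleases
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computational procedures for characterizing Type V-A (Cas12a-like)
    CRISPR nucleases from cleavage-assay sequencing data. Includes a synthetic
    read simulator that emulates an 8N randomized-PAM plasmid library cleaved
    by a nuclease with a configurable PAM preference and staggered cut
    geometry; a PAM/cut-site caller that applies quality filtering, exact
    anchor and adapter matching, cut-site frequency filtering, and
    information-content profiling to recover PAM consensus motifs and the
    target-strand cut position; a CRISPR direct-repeat stem-loop motif scanner
    and universal single-guide RNA designer; and a transparent amplicon
    editing-outcome classifier and frequency estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: CRISPR, Sequencing, SequenceMatching, Alignment, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'crisprVA-package.R'
    'objects.R'
    'editquant.R'
    'guidescan.R'
    'io.R'
    'simlib.R'
    'pamcall.R'
    'plot.R'
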