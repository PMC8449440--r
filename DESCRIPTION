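Package: mitesat
Title: Annotation and Comparative Analysis of Microsatellite-Associated MITEs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize miniature inverted-repeat transposable
    elements (MITEs) that associate with dinucleotide microsatellites.
    Provides full-length element calling from RepeatMasker annotations,
    classification of elements into microsatellite-targeting (mt) and
    Mutator-like (ml) groups from flanking microsatellite runs and 9/10-bp
    target site duplications, Kimura two-parameter divergence landscapes
    against family consensus sequences, detection of adjacent-insertion
    clusters, genome-to-genome and read-pair presence/absence-variation
    (PAV) calling, sliding-window density tracks and genomic-context,
    methylation and expression association. A synthetic-genome module
    plants elements with known class, divergence, clustering and
    inter-genome fate so every step can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
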