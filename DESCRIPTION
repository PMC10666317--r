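Package: mitokit
Title: Characterization of Plant Mitochondrial Genomes from Long Reads
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for desk-scale characterization of plant mitochondrial
    genomes: iterative core-gene-baited recruitment of organelle long reads
    from mixed-origin pools, C-to-U RNA editing codon-effect classification
    with a hydropathy-transition taxonomy, relative synonymous codon usage,
    microsatellite/tandem/dispersed repeat mining, quantification of
    plastid-derived homologous fragments (MTPT), and pairwise Ka/Ks (NG86 and
    modified LWL) together with nucleotide diversity. A seeded synthetic-data
    generator produces circular mitogenomes with planted genes, repeats,
    plastid insertions and editing sites, plus labelled mixed-origin long
    reads, for validation of every stage against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    seqinr,
    ape
Config/testthat/edition: 3
biocViews: Genetics, Sequencing, Alignment, RepeatAnalysis
RoxygenNote: 7.3.3
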