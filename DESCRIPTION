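Package: plastarch
Title: Comparative Plastome Architecture and Molecular Evolution
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of plastid genome (plastome)
    architecture: detection of the inverted repeat and the quadripartite
    LSC/IRA/SSC/IRB partition of circular genomes, per-region length and
    G/C statistics, IR-junction gene tables, signed gene-order comparison
    (breakpoint distances, oriented synteny blocks, inversion candidates,
    region translocations), simple indel coding of alignment gaps into
    binary character matrices with Fitch small-parsimony classification
    (synapomorphic / autapomorphic / homoplastic), Wright's effective
    number of codons (ENc) and nucleotide composition, and pseudogene /
    RNA-editing screens. Includes ground-truthed synthetic plastome,
    gene-order, indel-alignment and codon-usage generators so the whole
    pipeline is testable end to end, plus readers and writers for GenBank
    flat files, FASTA, NEXUS matrices with exclusion sets and character
    state labels, and Newick trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
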