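Package: oligodesign
Title: Oligonucleotide Design for PCR- and LCR-Based Gene Assembly
Version: 0.1.0
Authors@R:
    person("Open", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Splits a long DNA sequence into a set of overlapping
    oligonucleotides suitable for gene synthesis by polymerase chain
    reaction (PCR) or ligase chain reaction (LCR) assembly. Overlap
    regions are segmented to uniform melting temperature by an iterative
    boundary-refinement algorithm, then further equalized by a pruned
    depth-first search that shrinks overlap ends and introduces
    single-strand gaps for gapped PCR assembly. Melting temperatures are
    computed with the nearest-neighbor model using the SantaLucia (1998)
    unified thermodynamic parameters with monovalent-salt and strand
    concentration corrections. Includes a command-line interface, FASTA
    and TSV report writers, and seeded synthetic sequence generators for
    fully reproducible testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
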