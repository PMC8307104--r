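Package: mitocompare
Title: Comparative Analysis of Annotated Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative mitogenomics of annotated circular
    mitochondrial genomes: feature-table and GenBank flat-file input,
    coordinate/strand/spacer accounting, nucleotide composition and
    AT/GC-skew statistics per region and codon position, relative
    synonymous codon usage (RSCU) under the invertebrate mitochondrial
    code, Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor
    correction, template-constrained tRNA cloverleaf folding, and
    assembly of partitioned PCG+rRNA supermatrices with neighbor-joining
    smoke trees. Includes a seeded simulator of mitogenome-like clades
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
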