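Package: prgtyper
Title: Population Reference Graphs for HLA-Style Genotyping from Short Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds population reference graphs (PRGs) from layered multiple
    sequence alignments of gene alleles (exonic, genomic and regional-haplotype
    tiers), maps paired-end short reads directly to the graph with a
    seed-and-extend likelihood model, and infers diploid genotypes at G group
    resolution with quality metrics. Includes a k-mer based read pre-filter, a
    brute-force alignment oracle for validation, and a synthetic allele
    database and read simulator so the whole pipeline can be exercised without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: C++11
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
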