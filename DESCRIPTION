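Package: loxscan
Title: Detection and Quantification of Cre/loxPsym-Mediated Genome
    Rearrangements from Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing SCRaMbLE-style genome rearrangements in
    yeast strains carrying sparsely distributed loxPsym sites. Builds an
    in-silico junction reference from loxPsym flanking sequences,
    classifies loxPsym-containing long reads as parental or rearranged,
    computes depth-normalised rearrangement statistics (RR, ARR, RW),
    deduces copy number and loss of heterozygosity around loxPsym loci in
    hetero-diploids, and reconstructs the segment arrangement of a
    rearranged chromosome by Eulerian-path deconvolution. Includes a
    Cre-recombination and long-read simulator so every stage can be
    verified against a ground-truth event log.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
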