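Package: skimprov
Title: Archaeogenetic Identification of Degraded Specimens from Genome Skims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify a degraded (ancient or historical) specimen from
    low-coverage shotgun ("genome skim") sequencing reads. Implements a
    deterministic k-mer-seeded ungapped read mapper, competitive species
    screening against a panel of candidate reference genomes,
    cytosine-deamination damage profiling for ancient-DNA authentication,
    genetic sex estimation from chromosome-length-normalized read ratios, an
    f3 admixture test with a weighted block jackknife, depth-masked
    mitochondrial consensus calling, and neighbor-joining phylogenetic
    placement with bootstrap support. A seeded simulator generates
    ancient-DNA-like read sets with known ground truth so the whole workflow
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
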