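Package: tetrabin
Title: Metagenome Binning with Probabilistic Tetranucleotide and Abundance Distances
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Groups assembled metagenomic contigs into genome bins by
    integrating an empirically calibrated tetranucleotide-frequency distance
    probability (a size-aware logistic posterior that two contigs derive from
    different genomes) with an abundance distance probability (the non-shared
    area of per-sample normal coverage distributions, combined geometrically
    across samples), and clustering the composite distance with a modified
    iterative medoid algorithm. Includes a synthetic-community generator with
    ground truth and a base-weighted precision/recall evaluator, so the whole
    method is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rsamtools,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
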