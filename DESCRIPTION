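Package: taxmerge
Title: Ensemble Merging of Metagenomic Taxonomic Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates taxonomic profiles produced by multiple metagenome
    classifiers (profilers and binners) into a single enhanced per-sample
    profile. Co-occurrence of a taxon across tools is weighed against how many
    tool reference databases could have identified it, yielding a score used
    to bin taxa and filter likely false positives at a tunable
    precision-sensitivity trade-off; abundances are combined by the harmonic
    mean. Includes readers and writers for the BioBoxes/CAMI profiling and
    binning formats, NCBI-style taxonomy dump parsing with merged-id
    resolution, reference-length-normalized abundance estimation from binning
    output, per-rank evaluation metrics (sensitivity, precision, L1 norm),
    and a synthetic ensemble generator for end-to-end testing without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
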