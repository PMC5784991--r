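Package: hybridworms
Title: Dual-Marker Hybrid Detection and Mating Simulation for Eisenia Earthworms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects interspecific hybrids of the composting earthworms
    Eisenia andrei and E. fetida from paired mitochondrial (COI) and nuclear
    (28S rRNA) sequence markers. Discovers species-diagnostic alignment sites,
    calls diploid nuclear genotypes (AA/FF/AF) from IUPAC-ambiguity-coded
    Sanger consensus sequences, assigns maternal COI haplogroups (a/f/f2) by
    uncorrected p-distance, and composes the four-letter genotype codes used
    to label individuals (e.g. aAF). A gamete-inheritance model enumerates
    self-, facilitated-self- and cross-fertilization scenarios for any parent
    pair, checks multi-generation pedigrees for consistency, and a hybrid
    census reproduces headline counts from a family table. A forward mating
    simulator generates synthetic reference panels, cocoon/hatchling records
    under calibrated reproductive rates with asymmetric hybridization, and a
    binomial maximum-likelihood estimator recovers hybridization rates with
    Clopper-Pearson intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
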