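Package: chemotaxa
Title: Integrative Chemotaxonomy of Cryptic Species from Cuticular
    Hydrocarbons, Morphometrics and COI Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for delimiting cryptic insect species by combining
    cuticular hydrocarbon (CHC) chemotyping, multivariate ratio analysis of
    linear morphometric measurements, and COI population genetics.  The core
    is a haplotype-network-style "chemical network" algorithm that
    discretizes clr-transformed compositional GC-MS profiles along principal
    component axes and joins the resulting chemical types by a minimum
    spanning network.  Around it: Kovats retention indices, substance-class
    filtering and aggregation, Bray-Curtis/PERMANOVA/Mantel compositional
    statistics, shape PCA with PCA ratio spectra, pairwise PhiST and Tajima's
    D, climate-PCA logistic association models, and a synthetic-data
    generator that emulates the statistical structure of a two-chemotype,
    two-clade parabiotic ant system for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    broom,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
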