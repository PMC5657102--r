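Package: rareburden
Title: Burden Testing of Rare Germline and Somatic Variants with a
    Hidden Markov Random Field Selection Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A collapsing (burden-test) pipeline for case/control studies of
    rare germline and somatic variants. Candidate causal variants are selected
    by a hidden Markov random field over per-site carrier evidence, with
    interaction weights derived from tumour/normal variant allelic frequencies,
    neighbourhoods constrained to four-gamete-compatible intervals, and
    singular cases removed by genotype posterior probabilities before the
    selected variants are collapsed into a virtual locus and tested for
    association. Includes a fixed-number case/control simulator (Wright's
    distribution minor allele frequencies, population-attributable-risk
    driven relative risks), a null-model generator, and power / error-rate
    evaluation across replicate datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
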