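Package: sigfx
Title: Signature-Attributable Cancer Effect Sizes from Somatic Variant Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how much of the selective advantage conferred
    by recurrent somatic variants is attributable to individual mutational
    processes. The pipeline reads MAF-style variant tables, applies
    post-calling quality filters, deconvolves per-tumor mutational-signature
    weights from 96-channel trinucleotide spectra by forward selection with
    non-negative least squares, converts weights and gene-level baseline
    rates into per-variant per-tumor mutation rates, estimates each recurrent
    variant's cancer effect size by maximum likelihood under a Poisson
    fixation model, and attributes effects to signatures through the
    posterior probability that each signature generated the variant's
    trinucleotide context. Includes an APOBEC TC-motif substrate scanner and
    a synthetic-cohort generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    pracma,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
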