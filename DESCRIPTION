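Package: cnvlite
Title: Copy-Number Variant Calling from VCF Read Depth and B-Allele Frequency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects copy-number variants and alterations directly from
    whole-genome VCF files, using the per-site read depth (DP) and allele
    depth (AD) FORMAT fields. Computes binned read-depth signals in
    copy-number units with GC correction, per-bin B-allele-frequency
    likelihood curves from heterozygous sites, a mean-shift read-depth
    segmenter, and a joint read-depth plus B-allele-frequency caller that
    genotypes segments into deletion, duplication or copy-neutral loss of
    heterozygosity with an estimated cell fraction. Signals, likelihoods and
    calls persist in a documented multi-resolution HDF5 store. A simulator
    generates synthetic VCFs with ground-truth depth and event tables, and a
    concordance harness compares VCF-derived against alignment-like signals
    and call sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    vcfR,
    rhdf5,
    jsonlite,
    ggplot2,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
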