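Package: splicegrammar
Title: Splice-Site Sequence Grammar, Differential Splicing, and
    Bulked-Segregant Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the sequence grammar of 5' splice sites and
    its consequences for alternative splicing. Builds log-transformed
    position-specific scoring matrices from annotated splice sites, scores
    the U5 snRNA loop 1 (-2..-1) and U6 snRNA ACAGA box (+3..+5) interaction
    potential of individual donors, and classifies sites into the //GURAG and
    AG//GU major classes. Detects local alternative-splicing events (A5, A3,
    RI, SE) from transcript models, computes percent-spliced-in (PSI) values
    from transcript abundances, and fits per-event linear models of PSI on
    genotype, temperature, and their interaction with Benjamini-Hochberg
    correction. Includes positional composition statistics (G-tests,
    contingency tables, Spearman correlations), a bulked-segregant analysis
    scan for EMS-induced mutations (per-SNP G-tests smoothed with a tri-cube
    kernel), and seed-deterministic simulators that generate FASTA/GTF/VCF
    fixtures with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    knitr,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
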