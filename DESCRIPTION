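Package: subgenomics
Title: Subgenome Phasing, Homeologous Exchange Detection, and Ancestry
    Painting for Allopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting paleo-allopolyploid genomes without access
    to extant progenitor species. Identifies subgenome-diagnostic k-mers from
    differential repeat content, partitions chromosomes into subgenomes by
    clustering, segments chromosomes into ancestry blocks with a two-state
    hidden Markov model to call reciprocal homeologous exchanges, dates
    transposon bursts and hybridization from LTR-LTR and synonymous-site
    divergence under the Jukes-Cantor model, quantifies subgenome bias in
    gene retention (exact tests) and homeolog expression (median ratios and
    fold counts), and paints chromosomes of admixed accessions of ploidy 2-4
    with per-window ancestry dosage from allele read depths. Includes a
    synthetic allotetraploid data generator with planted ground truth so
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
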