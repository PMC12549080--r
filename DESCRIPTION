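Package: bsamapr
Title: Bulked-Segregant Mapping and Transposon Genotyping for Mutant Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for mapping a mutant locus from
    pooled resequencing of an F2 cross and for population-scale transposon
    presence/absence genotyping. Implements the MutMap+-style scan
    (per-site SNP indices, EMS transition filtering, delta SNP index,
    five-SNP sliding windows, candidate-region calling), recombinant-based
    interval delimitation and interval intersection, transposon genotyping
    from breakpoint-spanning reads with flank-uniqueness checks, and the
    accompanying segregation and association statistics. A synthetic-data
    module simulates every input the pipeline consumes: F2 populations
    with a planted causal locus, pooled allele counts under a Haldane
    recombination model, EMS-spectrum variant lists, junction reads, and
    accession panels with genotype-dependent phenotypes.
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
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
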