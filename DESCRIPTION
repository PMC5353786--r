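Package: dremap
Title: Differential Regulatory Element Mapping from Bisulfite Methylation Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps regulatory elements gained and lost between a cancer and a
    control sample class from per-CpG bisulfite sequencing methylation counts.
    Combines per-sample CpG profiles into a read-weighted class consensus,
    segments the consensus into hypomethylated (active) and highly methylated
    regions, and contrasts the two class maps into gained, lost and shared
    regulatory elements. Downstream statistics link regions to nearest-TSS
    genes and test enrichment near differentially expressed genes, test GWAS
    trait-SNP enrichment by label permutation after linkage-disequilibrium
    expansion of tag SNPs, call cancer-associated SNP alleles from pooled read
    counts with an exact binomial comparison, test haplotype association of
    called alleles with GWAS risk alleles, and quantify transcription factor
    binding site gain and loss under allele substitution with position weight
    matrix scanning. A seeded synthetic-data generator produces every input
    with planted ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    seqinr,
    vcfR,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
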