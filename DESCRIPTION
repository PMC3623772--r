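Package: balsel
Title: Detection of Ancient Balanced Polymorphism from Phased Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting long-term balancing selection and ancient
    population substructure at haplotype blocks from phased diploid genotypes.
    Implements windowed diversity and selection statistics (nucleotide
    diversity, Watterson's theta, Tajima's D with coalescent-simulation
    p-values, Hudson's FST, pairwise linkage disequilibrium) with genome-wide
    empirical outlier p-values and a multi-statistic quadrant filter;
    tag-SNP haplogroup classification with haplotype PCA and within-group
    diversity contrasts; comparison of modern haplotypes to an archaic
    consensus, read-depth deletion genotyping and deletion breakpoint mapping
    with micro-homology handling; median-joining haplotype networks with
    rho-statistic coalescence dating; a maximum-likelihood multilocus HKA
    test; and a coalescent generator of synthetic data sets with two deeply
    diverged haplogroups, a linked deletion allele and an archaic lineage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    igraph,
    GenomicRanges,
    IRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
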