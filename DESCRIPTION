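Package: cryptaxon
Title: Delineating Cryptic Mosquito Taxa from Population Genomic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for the population-genomic inference
    chain used to delineate cryptic taxa within the Anopheles gambiae
    species complex: site filtering and linkage-disequilibrium pruning,
    Patterson-scaled principal component analysis and ancestry-informative
    marker (AIM) fractions, windowed diversity and divergence scans (pi,
    Watterson's theta, Tajima's D, Hudson/Bhatia FST, Dxy, folded site
    frequency spectra), f3 and Patterson's D admixture statistics with
    block-jackknife significance, discovery of taxon-diagnostic SNP panels
    and individual classification by allelic percentage, Garud H12
    haplotype-homozygosity selection scans with window-size calibration,
    coverage-based copy-number calling with a Gaussian hidden Markov model,
    and per-cohort amino-acid substitution frequency reporting. A synthetic
    data module (Balding-Nichols allele-frequency divergence, admixture,
    selective sweeps, copy-number truth tracks with GC bias) provides
    ground-truthed fixtures so every stage is testable without the original
    sequencing resource.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    vcfR,
    GenomicRanges,
    yaml,
    jsonlite,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
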