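Package: rhosplit
Title: Allele-Split Association Mapping of Meiotic Recombination Hotspots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens phased SNP haplotype panels for variants whose alleles are
    associated with differing intensities of nearby meiotic recombination
    hotspots. Haplotypes are split by the alleles of a candidate SNP, a
    penalized product-of-approximate-conditionals (PAC) composite likelihood
    estimates a per-interval population recombination rate profile for each
    subpopulation, and the normalized difference of hotspot strengths,
    (rho0 - rho1)/(rho0 + rho1), is tested against a size-matched permutation
    null. Ships a forward-time Wright-Fisher simulator in which one allele of
    a causal SNP raises the crossover probability at a central hotspot (the
    benchmark data generator), readers and writers for the LDhat sites/locs
    haplotype dialect, and a motif stage that extracts sequence windows around
    significant SNPs, plants benchmark motifs, and discovers position weight
    matrices with a one-occurrence-per-sequence EM finder.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
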