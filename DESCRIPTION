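Package: rohdiv
Title: Runs of Homozygosity, Inbreeding Coefficients and Effective
    Population Size for SNP-Array and Pedigree Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genetic-diversity analysis for livestock populations genotyped
    on SNP arrays with accompanying pedigrees. Detects runs of homozygosity
    (ROH) with the overlapping-window method and calibrates the minimum run
    length from the genotype panel; computes genomic inbreeding coefficients
    (F_ROH overall, by length class and by length threshold, F_HOM, F_IS and
    the GCTA F-hat estimators), classical and ancestral pedigree inbreeding
    (Meuwissen-Luo F, equivalent generations, individual rate of inbreeding,
    and gene-drop coefficients of Ballou, Kalinowski and Baumung); estimates
    effective population size trajectories from linkage-disequilibrium decay
    and from closed forms on mean F_ROH; and maps consensus ROH and
    percentile-threshold ROH islands with optional gene annotation. Ships a
    pedigree-and-genotype simulator with known identity-by-descent truth so
    the whole workflow runs without restricted data, plus PLINK bed/bim/fam
    and ped/map input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Config/testthat/edition: 3
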