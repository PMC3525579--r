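Package: invclines
Title: Inversion-Partitioned Population Genetics Along Latitudinal Clines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of phased multiallelic haplotypes grouped by chromosomal
    inversion (gene arrangement): gene diversity, haploid F_ST variance
    components with permutation tests and between/within-arrangement
    partitions, multiallelic linkage disequilibrium (D'm, interallelic D',
    Ohta's D-statistics), isolation-by-distance Mantel regressions,
    latitudinal cline regressions of arrangement and allele frequencies, and
    an fdist-style F_ST-outlier scan against an island-model coalescent null.
    Includes a synthetic-data generator emulating a multi-population clinal
    sampling design for end-to-end testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    geosphere,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
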