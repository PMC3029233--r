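Package: pscnseg
Title: Parent-Specific DNA Copy Number Estimation from SNP Array Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates parent-specific DNA copy number in tumor samples from
    allele-specific SNP-array signals. Fits a continuous-state two-chromosome
    hidden Markov model by alternating Gaussian-mixture forward/backward
    smoothing (with bounded-complexity mixture pruning) and maximum a
    posteriori genotyping, produces a hard segmentation with rank-sum based
    merging, estimates major and minor copy numbers per segment by a
    two-component EM on heterozygous SNPs, and classifies each aberrant
    region into one of six types of chromosomal change, including copy
    neutral loss of heterozygosity. Includes a synthetic tumor-dilution
    generator for benchmarking under normal-cell contamination.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
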