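Package: sdscan
Title: Mapping Haploid-Acting Segregation Distortion from Pooled Gamete
    Sequencing
Version: 0.1.0
Authors@R:
    person("Paloma", "Reyes", email = "paloma.reyes@example.org",
           role = c("aut", "cre"))
Description: Detects, fine-maps and quantifies haploid-acting segregation
    distortion loci by comparing allele counts at ancestry-informative SNPs
    between a bulk gamete (e.g. pollen) library and a somatic library from
    the same F1 hybrid. Implements site filtering for ancestry-informative
    markers, physical-to-genetic map interpolation with Haldane's mapping
    function, a chromosome-wide binomial likelihood of germline read counts
    around a candidate distorter, a likelihood-ratio position scan with
    site-bootstrap mapping confidence intervals, a seeded simulator for
    power / false-positive / coverage calibration, and closed-form gamete
    viability and distorter-rate calculators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
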