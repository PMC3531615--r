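Package: divergekit
Title: Population Divergence Dating from Mitochondrial Sequences and Microsatellites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dating population splits from mitochondrial sequence
    alignments and microsatellite genotypes. Implements sequence diversity
    statistics (haplotype and nucleotide diversity), Tamura-Nei (TN93)
    distances with gamma rate heterogeneity, AMOVA-based pairwise Phi-ST with
    permutation tests, an exact test of population differentiation,
    microsatellite statistics (expected heterozygosity, Weir-Cockerham theta,
    R-ST, delta-mu-squared, the stepwise-weighted distance D-SW, and the
    proportion-of-shared-alleles distance D-PS), a coalescent
    heterozygosity-excess bottleneck test under stepwise and two-phase
    mutation models, outgroup-calibrated substitution rates, and three
    divergence-time estimators with confidence-interval propagation. A
    built-in two-population split coalescent simulator with an outgroup
    lineage (HKY sequence mutation with gamma site rates; SMM/TPM
    microsatellite mutation) provides synthetic data with known truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
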