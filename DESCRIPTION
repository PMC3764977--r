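Package: ibdscreen
Title: Detection of Cryptic Relatedness in Nominally Unrelated Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnoses undocumented close relationships among nominally
    unrelated study subjects genotyped at SNPs, as arise in candidate-gene
    association studies.  Pairwise identity-by-descent (IBD) coefficients
    (k0, k1, k2) are estimated by a bias-corrected method of moments using
    exact finite-sample conditional identity-by-state probabilities.
    Reference clusters for common close relationships (duplicates/MZ twins,
    parent-offspring, full siblings, half siblings, first cousins, or
    user-supplied pedigrees) are built by gene-drop simulation with founder
    haplotypes drawn from a Markov haplotype-frequency model that captures
    linkage disequilibrium, so that markers need not be thinned to
    independence.  Study pairs whose estimated coefficients fall inside a
    relationship's bivariate-normal prediction ellipse and outside the
    (Bonferroni-adjusted) unrelated ellipse are flagged automatically.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
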