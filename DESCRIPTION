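Package: polyloc
Title: Localization of a Dominant Trait Locus from Backcross GWAS and
    Resequencing Selection Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for mapping a completely dominant Mendelian
    trait (modelled on polydactyly in the Beijing fatty chicken) from a
    three-generation backcross cohort and small divergent resequencing
    panels. Includes simulation of the mapping cohort under Balding-Nichols
    founder divergence and Haldane recombination, SNP quality control
    (MAF, missingness, exact Hardy-Weinberg test, LD pruning),
    identity-by-state multidimensional scaling, case/control association by
    logistic regression with Firth correction and by a GRM-based mixed
    linear model, Weir-Cockerham F_st sliding-window outlier scanning,
    opposite-homozygote detection, nearest-gene annotation, and
    penetrance/segregation analysis of breeding designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
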