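Package: feralmix
Title: Ancestry, Relatedness and Runs-of-Homozygosity Analysis for SNP-Array Genotype Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the genetic ancestry of admixed populations
    genotyped on SNP arrays against a panel of reference clusters. Reads and
    writes PLINK text (.ped/.map) and binary (.bed/.bim/.fam) genotype files,
    merges panels on shared markers with allele-orientation reconciliation,
    applies call-rate quality filters, estimates pairwise relatedness
    (method-of-moments IBD) for duplicate pruning, fits supervised and
    unsupervised admixture models by expectation-maximization with
    locus-bootstrap standard errors, projects query samples onto reference-
    defined principal components, detects runs of homozygosity under density,
    gap and heterozygote constraints, and summarizes genomic inbreeding (fROH).
    Includes a synthetic-panel generator (Balding-Nichols divergence model)
    providing ground-truth fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
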