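Package: breedacc
Title: Expected Accuracy of Predicted Breeding Values under Genetic Erosion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to quantify the erosion in the accuracy of predicted
    breeding values (PBV) when the non-phenotyped target population drifts
    away from the phenotyped reference population. Implements the animal
    model with pedigree (A), genomic (G) or single-step (H) relationship
    matrices, restricted maximum likelihood for the variance components,
    BLUP/PBV solutions, two estimators of the index of genetic correlation
    (IGC) between populations -- one based on singular-value decompositions
    of the centred and scaled genotype matrices, one based on Fisher
    Z-regression of accuracies from simulated phenotypes -- and the
    Fisher-Z expectation of the realized accuracy given erosion. A forward
    simulator of LD-structured SNP genotypes with recombination and random
    mating makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
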