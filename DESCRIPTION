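Package: phenofun
Title: Inferring Gene Ontology Functions from Mutant Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers Gene Ontology (GO) functions for genes from
    mutant-phenotype annotations using the Entity/Quality (EQ) logical
    definitions of phenotype-ontology terms, and evaluates the inferred
    annotations by their ability to predict genetic and protein-protein
    interactions through superclass-closure Jaccard functional similarity
    and ROC analysis. Includes parsers for OBO ontologies and
    cross-product definition files, GAF annotation files, phenotype
    tables, genotype-to-gene maps and interaction datasets (GAF IGI/IPI,
    STRING, BioGRID), plus a seeded synthetic-world generator with known
    ground truth for end-to-end testing without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, tools, graphics, yaml
Suggests: testthat (>= 3.0.0), withr, pROC, jsonlite, optparse
Config/testthat/edition: 3
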