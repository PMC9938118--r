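Package: genofirst
Title: Genetics-First Prediction of Phenotype Outliers from Missense Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts, for each term of a biomedical ontology, which
    individuals are genetic outliers relative to a background cohort, before
    any phenotype is observed. Missense variants are weighted by the
    evolutionary intolerance of the substitution, measured as the log-odds
    between profile-HMM match-state emission probabilities, and collapsed
    into per-term variant profiles via domain-to-term maps. All-against-all
    genetic distances feed spectral clustering to detect hidden structure in
    the genetic landscape of a term; per-individual outlier scores combine
    within-cluster and between-cluster distances with an exponential
    cluster-size penalty, and are transformed to a scale comparable across
    terms. Above-threshold calls are explained by variant ablation
    (required versus contributing variants, four outlier types, minor-allele
    frequency classes, combinatorial contribution) and confirmed against
    phenotype answer tables by permutation tests. A synthetic-cohort
    generator produces every input format so the full pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
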