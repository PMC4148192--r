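Package: plnet
Title: Phenotypic-Linkage Networks and Confounder-Matched Gene-Set Clustering Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds integrated functional gene networks calibrated to
    phenotype-ontology semantic similarity. Scores gene pairs from
    heterogeneous evidence (co-expression, physical interactions, annotation
    vocabularies, pre-scored pair lists), evaluates each evidence source
    against a phenotype benchmark by binned median semantic similarity
    (Resnik similarity with disjunctive common ancestors), rescores included
    sources onto the benchmark scale by linear regression, and integrates
    them with a rank-down-weighted evidence sum. Tests gene sets for excess
    internal link weight with permutation nulls that match coding-sequence
    length or node degree, controlling the mutability bias of long genes.
    Includes a synthetic-data generator emulating ontologies, annotations,
    noisy evidence, and length-coupled networks so that every stage of the
    pipeline can be exercised and calibrated without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
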