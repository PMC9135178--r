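Package: ncmetab
Title: Rule-Based Prediction and Ranking of In Vivo Metabolites for Natural Compounds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts in vivo metabolites of natural compounds by applying
    enzyme-free biotransformation rules written as reaction SMARTS, ranks the
    candidate products by an optimized functional-group priority order with a
    topological steric-hindrance fine sort, and evaluates predictions with a
    combined coverage and sorting-ability (CS) score. Includes an exhaustive
    enumerator over the 40,320 orderings of the eight functional-group
    categories, substrate-metabolite pair dataset I/O, an external rank-list
    scoring mode, and seeded fixture generators with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
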