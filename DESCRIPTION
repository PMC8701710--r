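Package: medsql
Title: Grammar-Constrained Text-to-SQL Generation for Electronic Medical Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Translates natural-language questions about electronic medical
    records into executable SQL. Questions are linked to a relational schema
    by longest-first n-gram matching, encoded together with the schema by a
    self-attention encoder, and decoded under a 24-rule context-free grammar
    into a tree-structured intermediate representation that renders
    deterministically to SQL. Includes a memory-enhanced column pointer,
    span pointers for condition values with ROUGE-L value recovery against
    database content, logic-form and execution accuracy metrics with a
    five-component breakdown, and a template-based synthetic corpus
    generator over a five-table EMR-style schema so the full pipeline can
    be trained and evaluated end to end on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
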