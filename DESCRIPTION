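Package: tosrr
Title: Tree-Organized Self-Reflective Retrieval for Question Answering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds tree-organized knowledge bases of subject-predicate-object
    triples bound to text chunks (SPO-T units) from hierarchically structured
    documents, retrieves knowledge through a dual-path (keyword and vector
    similarity) recall strategy with fixed fusion quotas, and answers questions
    through a bounded self-reflective generate-verify loop with pluggable
    language-model backends. Includes an evaluation harness for multiple-choice
    exam rounds, retrieval-quality metrics (context precision, context recall,
    context entity recall, semantic similarity), inter-rater agreement
    (Kendall's W), McNemar and paired t tests with effect sizes, percentile
    bootstrap intervals, and a seeded synthetic-corpus generator with planted
    ground truth so the whole pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
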