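Package: odsreg
Title: Semantically-Enabled Cancer Registry with Ontology-Driven Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and exploiting a semantically-enabled cancer
    registry at desk scale. Includes a stratified cohort simulator driven by
    stacked probability distributions (gender by 5-year age strata, diagnosis
    and therapy weights, monthly disease-course transitions), an
    ontology-driven transformation of tabular registry data into an RDF triple
    store, an incremental query model that compiles to SPARQL without the user
    writing query text, semantic patient profiles and disease-timeline
    analytics (individual and group-aggregated with conditional re-filtering),
    hypergeometric term enrichment of ICD-10 annotations across patient
    groups, and an empirical treatment-sequence tree recommender. Ships a
    self-contained minimal cancer-registry ontology in Turtle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
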