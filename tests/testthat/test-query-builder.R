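# Ontology-driven search: emission, templates, defined classes, dashboards.

table4_model <- function() {
  query_model("Patient", children = list(
    hop("hasDiagnosis", "Diagnosis", children = list(
      hop("hasPathologicalStructure", "Colorectal_cancer"))),
    filt("gender", "=", "M"),
    filt("age", ">=", 50),
    filt("age", "<=", 70),
    hop("hasTherapy", "Chemotherapy")))
}

test_that("emission is deterministic and uses the template variable scheme", {
  onto <- shipped_ontology()
  m <- table4_model()
  q1 <- build_query(m, onto)
  q2 <- build_query(m, onto)
  expect_identical(q1, q2)
  for (v in c("\\?s", "\\?a0", "\\?ta0", "\\?a01", "\\?ta01", "\\?a1",
              "\\?a2", "\\?a3", "\\?a4", "\\?ta4"))
    expect_match(q1, v)
  expect_match(q1, "str\\(\\?a1\\) = 'M'")
  expect_match(q1, "\\?a2 >= 50")
})

test_that("a model without filters selects over the root closure only", {
  q <- build_query(query_model("Patient"), shipped_ontology())
  expect_match(q, "SELECT DISTINCT \\?s WHERE \\{\\{\\?s rdf:type \\?t FILTER \\(\\?t IN \\(ods:Patient\\)\\)\\}\\}")
})

test_that("domain violations are rejected at build time", {
  onto <- shipped_ontology()
  # hasTherapy does not apply to Diagnosis targets' children classes
  bad <- query_model("Patient", children = list(
    hop("hasDiagnosis", "Diagnosis", children = list(
      filt("gender", "=", "M")))))   # gender's domain is Patient
  expect_error(build_query(bad, onto), class = "odsreg_validation_error")
  bad2 <- query_model("Patient", children = list(filt("age", ">=", "abc")))
  expect_error(build_query(bad2, onto), class = "odsreg_validation_error")
})

test_that("templates round-trip and instantiate parameter slots", {
  onto <- shipped_ontology()
  m <- table4_model()
  tmp <- withr::local_tempfile(fileext = ".json")
  save_template(m, tmp)
  back <- load_template(tmp)
  expect_identical(build_query(back, onto), build_query(m, onto))
  # parameter slot: same template instantiated at two ages differs only in
  # the literal
  slot <- query_model("Patient", children = list(filt("age", ">=", "?")))
  tmp2 <- withr::local_tempfile(fileext = ".json")
  save_template(slot, tmp2)
  q60 <- build_query(load_template(tmp2, params = list(age = 60)), onto)
  q70 <- build_query(load_template(tmp2, params = list(age = 70)), onto)
  expect_identical(gsub("60", "70", q60), q70)
  # un-instantiated slots cannot be compiled
  expect_error(build_query(load_template(tmp2), onto),
               class = "odsreg_validation_error")
})

test_that("dashboard templates persist aggregations", {
  onto <- shipped_ontology()
  # patients over 70, classified by cancer type: aggregation over the
  # pathological structure type of the diagnosis hop
  dash <- query_model("Patient", children = list(
    filt("age", ">", 70),
    hop("hasDiagnosis", "Diagnosis", children = list(
      hop("hasPathologicalStructure", "Pathological_structure")))),
    aggregation = aggregate_by("count", TRUE, "type"),
    name = "patients over 70 by cancer type")
  tmp <- withr::local_tempfile(fileext = ".json")
  save_template(dash, tmp)
  back <- load_template(tmp)
  expect_identical(build_query(back, onto), build_query(dash, onto))
  expect_equal(back$name, dash$name)
})

test_that("defined classes are virtual and recompute on demand", {
  reg <- build_test_registry(list(
    list(gender = "M", age = 61, dx = list(list(path = "Colorectal_cancer",
                                                icd = "C20", date = "2010-01-01"))),
    list(gender = "F", age = 58, dx = list(list(path = "Lung_cancer",
                                                icd = "C34.1", date = "2010-01-01")))))
  store <- transform_registry(reg, shipped_rules(), shipped_ontology())
  dc <- defined_class("Patient with colorectal cancer",
                      model_for(cancer = "Colorectal_cancer"))
  members <- register_defined_class(dc, store)
  expect_length(members, 1)
  # a query matching nothing yields the empty set
  dc0 <- defined_class("Patient with melanoma", model_for(cancer = "Melanoma"))
  expect_length(register_defined_class(dc0, store), 0)
  # name collisions with ontology classes are rejected
  expect_error(register_defined_class(defined_class("Patient",
                                                    model_for()), store),
               class = "odsreg_validation_error")
  # aggregating queries cannot define a class
  expect_error(defined_class("x", model_for(aggregation = aggregate_by())),
               class = "odsreg_validation_error")
  # membership grows when a matching patient is added (recomputed on demand)
  reg2 <- build_test_registry(list(
    list(gender = "M", age = 61, dx = list(list(path = "Colorectal_cancer",
                                                icd = "C20", date = "2010-01-01"))),
    list(gender = "F", age = 58, dx = list(list(path = "Lung_cancer",
                                                icd = "C34.1", date = "2010-01-01"))),
    list(gender = "F", age = 66, dx = list(list(path = "Colorectal_cancer",
                                                icd = "C18.9", date = "2011-01-01")))))
  store2 <- transform_registry(reg2, shipped_rules(), shipped_ontology())
  register_defined_class(dc, store2)
  expect_length(defined_class_members(dc$name, store2), 2)
})

test_that("dashboard results conserve totals over exhaustive disjoint groups", {
  reg <- sim_registry(n = 120, seed = 101)
  store <- sim_store(n = 120, seed = 101)
  dash <- query_model("Therapy",
                      aggregation = aggregate_by("count", TRUE, "type"))
  out <- dashboard_result(list(`therapies by class` = dash), store)
  tab <- out[[1]]$table
  expect_equal(sum(tab$value), nrow(reg$therapies))
  expect_identical(out[[1]]$label, "therapies by class")
  # empty store yields zero-row tables
  empty <- odsreg:::new_semantic_store(odsreg:::empty_triples(),
                                       shipped_ontology(), odsreg:::DEFAULT_NS)
  out0 <- dashboard_result(list(x = dash), empty)
  expect_equal(nrow(out0[[1]]$table), 0)
  # non-aggregating model is a validation error
  expect_error(dashboard_result(list(y = query_model("Patient")), store),
               class = "odsreg_validation_error")
})

test_that("closure filters equal the union of per-class type queries", {
  store <- sim_store(n = 40, seed = 23)
  onto <- shipped_ontology()
  for (root in c("Radiotherapy", "DrugTherapy")) {
    closure <- closure_locals(onto, root)
    whole <- run_query(query_model(root), store)$s
    parts <- unlist(lapply(closure, function(cl) {
      # restrict the type filter to exactly one class
      q <- paste0("PREFIX ods: <", store$namespace, ">\n",
                  "SELECT DISTINCT ?s WHERE {{?s rdf:type ?t FILTER (?t IN (",
                  "ods:", cl, "))}}")
      execute_sparql(store, q)$s
    }))
    expect_setequal(whole, unique(parts))
  }
})
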