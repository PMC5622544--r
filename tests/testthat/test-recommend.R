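# Treatment-sequence tree recommender.

seq_registry <- function(seqs) {
  # one patient per sequence; therapies start in consecutive months
  specs <- lapply(seqs, function(sq) {
    start <- as.Date("2010-01-01")
    ths <- lapply(seq_along(sq), function(i) list(
      class = sq[[i]],
      start = as.character(odsreg:::add_months(start, i - 1L)),
      end = as.character(odsreg:::add_months(start, i - 1L) + 14)))
    list(gender = "M", age = 60,
         dx = list(list(path = "Colorectal_cancer", icd = "C20",
                        date = "2010-01-01", therapies = ths)))
  })
  build_test_registry(specs)
}

test_that("first-period probabilities are empirical cohort fractions", {
  reg <- seq_registry(list(c("Chemotherapy", "Teletherapy"),
                           c("Chemotherapy"),
                           c("Chemotherapy", "Chemotherapy"),
                           c("SurgicalTreatment")))
  store <- transform_registry(reg, shipped_rules(), shipped_ontology())
  tree <- build_treatment_tree(store, query_model("Patient"))
  rec <- recommend_next(tree)
  expect_equal(rec$probability[rec$therapy == "Chemotherapy"], 0.75)
  expect_equal(rec$probability[rec$therapy == "SurgicalTreatment"], 0.25)
  # repeated application of the same therapy unrolls along the path
  rec2 <- recommend_next(tree, "Chemotherapy")
  expect_equal(rec2$probability[rec2$therapy == "Chemotherapy"], 1 / 3)
  expect_equal(rec2$probability[rec2$therapy == "Teletherapy"], 1 / 3)
  expect_equal(rec2$probability[rec2$therapy == odsreg:::NO_FURTHER], 1 / 3)
})

test_that("a single-patient cohort yields a degenerate all-ones tree", {
  reg <- seq_registry(list(c("Chemotherapy", "Teletherapy")))
  store <- transform_registry(reg, shipped_rules(), shipped_ontology())
  tree <- build_treatment_tree(store, query_model("Patient"))
  node <- tree$root
  while (length(node$children) > 0) {
    expect_length(node$children, 1)
    expect_equal(node$children[[1]]$prob, 1)
    node <- node$children[[1]]
  }
  # a full-depth leaf recommends only "no further therapy"
  rec <- recommend_next(tree, c("Chemotherapy", "Teletherapy"))
  expect_equal(rec$therapy, odsreg:::NO_FURTHER)
  expect_equal(rec$probability, 1)
})

test_that("node probabilities normalise and supports conserve exactly", {
  store <- sim_store(n = 120, seed = 101)
  tree <- build_treatment_tree(store, query_model("Patient"))
  check <- function(node) {
    if (length(node$children) == 0) return(invisible(NULL))
    probs <- vapply(node$children, `[[`, numeric(1), "prob")
    sups <- vapply(node$children, `[[`, numeric(1), "support")
    expect_equal(sum(probs), 1, tolerance = 1e-9)
    expect_equal(sum(sups), node$support)
    for (ch in node$children) check(ch)
  }
  check(tree$root)
  expect_equal(tree$root$support, tree$n_patients)
})

test_that("rankings equal a direct sequence group-by oracle", {
  store <- sim_store(n = 120, seed = 101)
  tree <- build_treatment_tree(store, query_model("Patient"))
  pats <- sort(unique(run_query(query_model("Patient"), store)$s))
  seqs <- odsreg:::therapy_sequences(store, pats, "month")
  for (path in list(character(0), "Chemotherapy",
                    c("SurgicalTreatment", "Chemotherapy"))) {
    matching <- Filter(function(s) length(s) >= length(path) &&
                         identical(s[seq_along(path)], unname(path)), seqs)
    if (length(matching) == 0) next
    nxt <- vapply(matching, function(s)
      if (length(s) > length(path)) s[[length(path) + 1L]] else
        odsreg:::NO_FURTHER, character(1))
    freq <- sort(table(nxt) / length(nxt), decreasing = TRUE)
    rec <- recommend_next(tree, path)
    expect_true(attr(rec, "exact_path"))
    for (cl in names(freq))
      expect_equal(rec$probability[rec$therapy == cl], unname(freq[[cl]]),
                   info = paste(c(path, "->", cl), collapse = " "))
    expect_equal(rec$probability[1], unname(freq[[1]]))
  }
})

test_that("an unseen path falls back to the nearest prefix, flagged", {
  reg <- seq_registry(list(c("Chemotherapy"), c("Teletherapy")))
  store <- transform_registry(reg, shipped_rules(), shipped_ontology())
  tree <- build_treatment_tree(store, query_model("Patient"))
  rec <- recommend_next(tree, c("Chemotherapy", "Brachytherapy", "Wait_and_see"))
  expect_false(attr(rec, "exact_path"))
  expect_equal(attr(rec, "used_path"), "Chemotherapy")
  # empty cohort is rejected
  expect_error(build_treatment_tree(store, model_for(cancer = "Melanoma")),
               class = "odsreg_validation_error")
})
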