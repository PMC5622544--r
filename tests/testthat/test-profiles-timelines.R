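# Semantic profiles, patient timelines, aggregated matrices, re-filtering.

test_that("profiles select datatype values and nested object profiles", {
  reg <- build_test_registry(list(list(
    gender = "M", age = 62,
    dx = list(list(path = "Colorectal_cancer", icd = "C20",
                   date = "2010-01-01")))))
  store <- transform_registry(reg, shipped_rules(), shipped_ontology())
  pat <- patient_iri(store, "P000001")
  prof <- extract_profile(store, pat, property_selection(
    datatype_props = "gender",
    object_props = list(hasDiagnosis = property_selection("icd10_code"))))
  expect_equal(prof$values$gender, "M")
  expect_length(prof$links$hasDiagnosis, 1)
  expect_equal(prof$links$hasDiagnosis[[1]]$values$icd10_code, "C20")
  # empty object selection degenerates to the datatype part only
  p2 <- extract_profile(store, pat, property_selection("gender"))
  expect_length(p2$links, 0)
  expect_equal(p2$values$gender, "M")
  expect_error(extract_profile(store, "http://nowhere/x",
                               property_selection("gender")),
               class = "odsreg_lookup_error")
})

test_that("profile extraction terminates on cyclic graphs and omits back-links", {
  # two mutually linked individuals A <-> B
  ns <- odsreg:::DEFAULT_NS
  tr <- odsreg:::triple_df(
    s = c(paste0(ns, "individual/patients/A"), paste0(ns, "individual/patients/B"),
          paste0(ns, "individual/patients/A"), paste0(ns, "individual/patients/B"),
          paste0(ns, "individual/patients/A"), paste0(ns, "individual/patients/B")),
    p = c(odsreg:::RDF_TYPE, odsreg:::RDF_TYPE,
          paste0(ns, "hasDiagnosis"), paste0(ns, "hasDiagnosis"),
          paste0(ns, "gender"), paste0(ns, "gender")),
    o = c(paste0(ns, "Patient"), paste0(ns, "Patient"),
          paste0(ns, "individual/patients/B"), paste0(ns, "individual/patients/A"),
          "M", "F"),
    o_kind = c("iri", "iri", "iri", "iri", "literal", "literal"),
    o_dt = c(NA, NA, NA, NA, "string", "string"))
  store <- odsreg:::new_semantic_store(tr, shipped_ontology(), ns)
  sel <- property_selection("gender", list(hasDiagnosis = property_selection(
    "gender", list(hasDiagnosis = property_selection(
      "gender", list(hasDiagnosis = property_selection("gender")))))),
    max_depth = 5)
  prof <- extract_profile(store, paste0(ns, "individual/patients/A"), sel)
  # terminated, and B's nested profile omits the back-link to A
  b <- prof$links$hasDiagnosis[[1]]
  expect_equal(b$values$gender, "F")
  expect_length(b$links, 0)
})

test_that("therapy month spans follow calendar-month overlap", {
  reg <- build_test_registry(list(list(
    gender = "F", age = 58,
    dx = list(list(path = "Breast_cancer", icd = "C50", date = "2010-01-01",
                   therapies = list(list(class = "Chemotherapy",
                                         start = "2010-01-15",
                                         end = "2010-03-10")))))))
  store <- transform_registry(reg, shipped_rules(), shipped_ontology())
  tl <- build_timeline(store, patient_iri(store, "P000001"))
  d <- tl$diagnoses[[1]]
  expect_setequal(d$therapy_months$month, c(0L, 1L, 2L))
  expect_true(all(d$therapy_months$class == "Chemotherapy"))
})

test_that("a therapy-free patient still carries course and Karnofsky tracks", {
  reg <- build_test_registry(list(list(
    gender = "M", age = 70, karnofsky = 80L,
    dx = list(list(path = "Prostate_cancer", icd = "C61", date = "2012-01-01",
                   courses = list(list(kind = "Stable_disease", order = 1L,
                                       date = "2012-01-01"),
                                  list(kind = "Progression", order = 2L,
                                       date = "2012-05-01")))))))
  store <- transform_registry(reg, shipped_rules(), shipped_ontology())
  tl <- build_timeline(store, patient_iri(store, "P000001"))
  d <- tl$diagnoses[[1]]
  expect_equal(nrow(d$therapy_months), 0)
  expect_equal(d$course_months$kind[d$course_months$month == 0], "Stable_disease")
  expect_equal(d$course_months$kind[d$course_months$month == 4], "Progression")
  expect_equal(d$karnofsky$value[d$karnofsky$month == 0], 80L)
  expect_equal(tl$last_encounter, "2012-05-01")
})

test_that("when two course events share a month the higher order wins", {
  reg <- build_test_registry(list(list(
    gender = "M", age = 60,
    dx = list(list(path = "Lung_cancer", icd = "C34.1", date = "2010-01-01",
                   courses = list(list(kind = "Stable_disease", order = 1L,
                                       date = "2010-02-03"),
                                  list(kind = "Progression", order = 2L,
                                       date = "2010-02-20")))))))
  store <- transform_registry(reg, shipped_rules(), shipped_ontology())
  tl <- build_timeline(store, patient_iri(store, "P000001"))
  cm <- tl$diagnoses[[1]]$course_months
  expect_equal(cm$kind[cm$month == 1], "Progression")
})

test_that("a one-patient matrix is that patient's event indicator", {
  store <- sim_store(n = 40, seed = 23)
  pats <- run_query(query_model("Patient"), store)$s
  p <- sort(pats)[1]
  mat <- aggregate_timelines(store, p)
  tl <- build_timeline(store, p)
  ev <- odsreg:::timeline_events(tl)
  expect_equal(sum(mat$counts), nrow(ev))
  expect_true(all(mat$counts %in% c(0L, 1L)))
})

test_that("matrix cells equal per-patient oracle sums", {
  store <- sim_store(n = 40, seed = 23)
  pats <- run_query(query_model("Patient"), store)$s
  mat <- aggregate_timelines(store, pats)
  # oracle: accumulate each patient's events independently
  expected <- new.env()
  for (p in pats) {
    ev <- odsreg:::timeline_events(build_timeline(store, p))
    for (i in seq_len(nrow(ev))) {
      key <- paste(ev$month[i], ev$category[i])
      expected[[key]] <- (expected[[key]] %||% 0L) + 1L
    }
  }
  for (m in mat$months) for (cat in mat$categories) {
    key <- paste(m, cat)
    expect_equal(mat$counts[as.character(m), cat],
                 expected[[key]] %||% 0L,
                 info = key)
  }
  # every cell bounded by the group size
  expect_true(all(mat$counts <= length(pats)))
})

test_that("re-filtering is idempotent, monotone and composes as intersection", {
  store <- sim_store(n = 40, seed = 23)
  pats <- run_query(query_model("Patient"), store)$s
  mat <- aggregate_timelines(store, pats)
  # monotone: every refiltered cell <= original cell
  sub <- refilter_matrix(store, mat, "Chemotherapy", first_therapy = TRUE)
  if (!sub$empty) {
    shared_m <- intersect(rownames(sub$counts), rownames(mat$counts))
    shared_c <- intersect(colnames(sub$counts), colnames(mat$counts))
    expect_true(all(sub$counts[shared_m, shared_c] <=
                      mat$counts[shared_m, shared_c]))
    # idempotent: a condition already satisfied by all leaves it unchanged
    again <- refilter_matrix(store, sub, "Chemotherapy", first_therapy = TRUE)
    expect_identical(again$counts, sub$counts)
    expect_identical(again$group, sub$group)
  }
  # oracle: subgroup = patients whose earliest therapy month has chemo
  keep <- vapply(sort(unique(pats)), function(p) {
    tl <- build_timeline(store, p)
    for (d in tl$diagnoses) {
      tm <- d$therapy_months
      if (nrow(tm) > 0 && "Chemotherapy" %in% tm$class[tm$month == min(tm$month)])
        return(TRUE)
    }
    FALSE
  }, logical(1))
  expect_setequal(sub$group, sort(unique(pats))[keep])
  # successive refilters equal the refilter with the conjunction
  s1 <- refilter_matrix(store, mat, "Chemotherapy", month = 0)
  s2 <- refilter_matrix(store, s1, "Progression", month = 2)
  direct <- vapply(sort(unique(pats)), function(p) {
    ev <- odsreg:::timeline_events(build_timeline(store, p))
    any(ev$month == 0 & ev$category == "Chemotherapy") &&
      any(ev$month == 2 & ev$category == "Progression")
  }, logical(1))
  expect_setequal(s2$group, sort(unique(pats))[direct])
  # a condition matched by nobody flags the empty group, not an error
  none <- refilter_matrix(store, mat, "Whole-body_irradiation", month = 0)
  expect_true(none$empty || length(none$group) > 0)
  # empty group input is a validation error
  expect_error(aggregate_timelines(store, character(0)),
               class = "odsreg_validation_error")
})
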