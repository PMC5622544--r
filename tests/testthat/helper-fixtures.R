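# Shared fixtures: memoised shipped models, a hand-controllable registry
# builder, and direct row-filter oracles used to cross-check the SPARQL
# route.

.fixture_env <- new.env(parent = emptyenv())

shipped_ontology <- function() {
  if (is.null(.fixture_env$onto)) .fixture_env$onto <- load_ontology()
  .fixture_env$onto
}

shipped_stack <- function() {
  if (is.null(.fixture_env$stack))
    .fixture_env$stack <- load_sim_config(ontology = shipped_ontology())
  .fixture_env$stack
}

shipped_rules <- function() {
  if (is.null(.fixture_env$rules))
    .fixture_env$rules <- load_mapping_rules(ontology = shipped_ontology())
  .fixture_env$rules
}

# Simulated store reused across test files (seed fixed; built once).
sim_store <- function(n = 120, seed = 101) {
  key <- paste0("store_", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    reg <- simulate_cohort(shipped_stack(), n, seed = seed)
    .fixture_env[[paste0("reg_", n, "_", seed)]] <- reg
    .fixture_env[[key]] <- transform_registry(reg, shipped_rules(),
                                              shipped_ontology())
  }
  .fixture_env[[key]]
}

sim_registry <- function(n = 120, seed = 101) {
  invisible(sim_store(n, seed))
  .fixture_env[[paste0("reg_", n, "_", seed)]]
}

# ---- hand-built registry -------------------------------------------------

# spec: list of patient specs; each is list(gender, age, dx = list(...)),
# each dx: list(path, icd, date, therapies = list(list(class, start, end)),
# courses = list(list(kind, order, date)))
build_test_registry <- function(specs) {
  pats <- list(); conds <- list(); dxs <- list(); ths <- list(); crs <- list()
  pk <- 0L; dk <- 0L; tk <- 0L; ck <- 0L; cok <- 0L
  for (sp in specs) {
    pk <- pk + 1L
    pid <- sprintf("P%06d", pk)
    first_dx <- sp$dx[[1]]$date
    birth <- as.character(as.Date(first_dx) - round(sp$age * 365.25) - 40)
    pats[[pk]] <- data.frame(patient_id = pid, gender = sp$gender,
                             birth_date = birth, stringsAsFactors = FALSE)
    cok <- cok + 1L
    conds[[cok]] <- data.frame(
      condition_id = sprintf("PC%06d", cok), patient_id = pid,
      ref_date = first_dx, age = sp$age, weight_kg = 70, height_cm = 170,
      karnofsky = sp$karnofsky %||% 90L, asa = 2L,
      menopause_status = if (sp$gender == "F") "postmenopausal" else "",
      stringsAsFactors = FALSE)
    for (dx in sp$dx) {
      dk <- dk + 1L
      did <- sprintf("D%06d", dk)
      dxs[[dk]] <- data.frame(
        diagnosis_id = did, patient_id = pid,
        icd10_code = dx$icd %||% "C80.9", grading = "G2", tnm_t = "T2",
        tnm_n = "N0", tnm_m = "M0", date = dx$date,
        pathological_structure = dx$path,
        anatomical_structure = dx$anat %||% "",
        tumor_type = dx$tumor %||% "carcinoma", stringsAsFactors = FALSE)
      for (th in dx$therapies %||% list()) {
        tk <- tk + 1L
        ths[[tk]] <- data.frame(
          therapy_id = sprintf("T%06d", tk), diagnosis_id = did,
          therapy_class = th$class, medication = th$med %||% "",
          start_date = th$start, end_date = th$end, stringsAsFactors = FALSE)
      }
      for (co in dx$courses %||% list()) {
        ck <- ck + 1L
        crs[[ck]] <- data.frame(
          course_id = sprintf("C%06d", ck), diagnosis_id = did,
          course_kind = co$kind, stage = "II", order = co$order,
          date = co$date, stringsAsFactors = FALSE)
      }
    }
  }
  bind <- function(x, proto) if (length(x) == 0) proto else do.call(rbind, x)
  structure(list(
    patients = bind(pats, NULL),
    conditions = bind(conds, NULL),
    diagnoses = bind(dxs, NULL),
    therapies = bind(ths, data.frame(
      therapy_id = character(0), diagnosis_id = character(0),
      therapy_class = character(0), medication = character(0),
      start_date = character(0), end_date = character(0))),
    courses = bind(crs, data.frame(
      course_id = character(0), diagnosis_id = character(0),
      course_kind = character(0), stage = character(0),
      order = integer(0), date = character(0)))),
    class = "registry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

patient_iri <- function(store, pid) {
  paste0(store$namespace, "individual/patients/", pid)
}

# ---- row-filter oracle ---------------------------------------------------

# Age of each patient as materialised in the store (first condition row).
oracle_ages <- function(reg) {
  cond <- reg$conditions[order(reg$conditions$patient_id,
                               reg$conditions$ref_date), ]
  first <- cond[!duplicated(cond$patient_id), ]
  stats::setNames(as.integer(first$age), first$patient_id)
}

closure_locals <- function(onto, class_local) {
  ns <- onto$namespace
  sub("^.*#", "", subclass_closure(onto, paste0(ns, class_local)))
}

# Patients satisfying a conjunction of constraints, by direct row filtering.
oracle_patients <- function(reg, onto, gender = NULL, age_min = NULL,
                            age_max = NULL, cancer = NULL, therapy = NULL) {
  ids <- reg$patients$patient_id
  if (!is.null(gender)) ids <- ids[reg$patients$gender[match(ids, reg$patients$patient_id)] == gender]
  ages <- oracle_ages(reg)
  if (!is.null(age_min)) ids <- ids[ages[ids] >= age_min]
  if (!is.null(age_max)) ids <- ids[ages[ids] <= age_max]
  if (!is.null(cancer)) {
    cl <- closure_locals(onto, cancer)
    keep <- reg$diagnoses$patient_id[reg$diagnoses$pathological_structure %in% cl]
    ids <- ids[ids %in% keep]
  }
  if (!is.null(therapy)) {
    cl <- closure_locals(onto, therapy)
    dids <- reg$therapies$diagnosis_id[reg$therapies$therapy_class %in% cl]
    keep <- reg$diagnoses$patient_id[reg$diagnoses$diagnosis_id %in% dids]
    ids <- ids[ids %in% keep]
  }
  sort(ids)
}

# Build the query model corresponding to the same constraints.
model_for <- function(gender = NULL, age_min = NULL, age_max = NULL,
                      cancer = NULL, therapy = NULL, aggregation = NULL) {
  children <- list()
  if (!is.null(cancer))
    children <- c(children, list(hop("hasDiagnosis", "Diagnosis", children =
      list(hop("hasPathologicalStructure", cancer)))))
  if (!is.null(gender)) children <- c(children, list(filt("gender", "=", gender)))
  if (!is.null(age_min)) children <- c(children, list(filt("age", ">=", age_min)))
  if (!is.null(age_max)) children <- c(children, list(filt("age", "<=", age_max)))
  if (!is.null(therapy)) children <- c(children, list(hop("hasTherapy", therapy)))
  query_model("Patient", children = children, aggregation = aggregation)
}

result_pids <- function(res, store) {
  sort(sub("^.*/patients/", "", res$s))
}
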