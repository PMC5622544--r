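# Disease timelines: per-patient month-normalised event tracks (therapies,
# course, Karnofsky) and group-aggregated month x category count matrices
# with conditional re-filtering.
#
# Month arithmetic is calendar-based (year*12 + month deltas), 0-based from
# the diagnosis date; a therapy contributes to every calendar month its
# [start, end] interval overlaps, partial months included.

# Store index for repeated timeline extraction: per-predicate lookup tables.
store_index <- function(store) {
  tr <- store$triples
  ns <- store$namespace
  pl <- iri_local(tr$p, ns)
  idx <- split(tr[, c("s", "o")], pl)
  types <- tr[tr$p == RDF_TYPE, c("s", "o")]
  type_of <- stats::setNames(types$o, types$s)
  list(idx = idx, type_of = type_of, ns = ns)
}

lookup_objs <- function(ix, prop, subj) {
  d <- ix$idx[[prop]]
  if (is.null(d)) return(character(0))
  d$o[d$s %in% subj]
}

lookup_val <- function(ix, prop, subj) {
  d <- ix$idx[[prop]]
  if (is.null(d)) return(NA_character_)
  v <- d$o[d$s == subj]
  if (length(v) == 0) NA_character_ else v[1]
}

#' Build the disease timeline of a patient
#'
#' For each diagnosis of the patient: the 0-based month index is the
#' calendar-month difference from the diagnosis date; therapies contribute
#' to every month their date interval overlaps; course events sit at their
#' month, sorted by (order, date), with at most one course kind per month
#' (the higher `order` wins); the Karnofsky series is taken from the
#' patient's conditions by month. The last-encounter date is the maximum
#' date over the patient's conditions, therapies and courses.
#'
#' @param store a `semantic_store`
#' @param patient patient IRI (typed `Patient` in the store)
#' @param index optional pre-built index from repeated extraction (internal)
#' @return an object of class `patient_timeline`: per diagnosis, data frames
#'   `therapy_months` (month, class), `course_months` (month, kind),
#'   `karnofsky` (month, value), plus `icd10`, `date`, `last_encounter`
#' @export
build_timeline <- function(store, patient, index = NULL) {
  ix <- index %||% store_index(store)
  ns <- ix$ns
  if (!identical(unname(ix$type_of[patient]), iri_expand("Patient", ns)))
    stop_odsreg("lookup", "%s is not a Patient in the store", patient)

  dxs <- sort_c(lookup_objs(ix, "hasDiagnosis", patient))
  dxs <- dxs[grepl("/diagnoses/", dxs)]
  conds <- sort_c(lookup_objs(ix, "hasPatientCondition", patient))
  cond_rows <- data.frame(
    ref = vapply(conds, function(cc) lookup_val(ix, "ref_date", cc), character(1)),
    karnofsky = vapply(conds, function(cc) lookup_val(ix, "karnofsky_index", cc),
                       character(1)),
    stringsAsFactors = FALSE)

  all_dates <- character(0)
  diagnoses <- list()
  for (d in dxs) {
    dx_date <- lookup_val(ix, "date", d)
    if (is.na(dx_date))
      stop_odsreg("data", "diagnosis %s has no date", d)
    ths <- sort_c(lookup_objs(ix, "hasTherapy", d))
    trows <- lapply(ths, function(t) {
      st <- lookup_val(ix, "start_date", t)
      en <- lookup_val(ix, "end_date", t)
      m0 <- months_between(st, dx_date)
      m1 <- months_between(en, dx_date)
      data.frame(month = m0:m1,
                 class = iri_local(unname(ix$type_of[t]), ns),
                 stringsAsFactors = FALSE)
    })
    therapy_months <- if (length(trows) == 0)
      data.frame(month = integer(0), class = character(0)) else
      unique(do.call(rbind, trows))
    crs <- sort_c(lookup_objs(ix, "hasDiseaseCourse", d))
    crows <- lapply(crs, function(cc) {
      data.frame(month = months_between(lookup_val(ix, "date", cc), dx_date),
                 kind = iri_local(unname(ix$type_of[cc]), ns),
                 ord = as.integer(lookup_val(ix, "order", cc)),
                 date = lookup_val(ix, "date", cc),
                 stringsAsFactors = FALSE)
    })
    course_months <- if (length(crows) == 0)
      data.frame(month = integer(0), kind = character(0)) else {
      cm <- do.call(rbind, crows)
      cm <- cm[order(cm$ord, cm$date), , drop = FALSE]
      cm <- cm[!duplicated(cm$month, fromLast = TRUE), c("month", "kind")]
      cm[order(cm$month), , drop = FALSE]
    }
    karnofsky <- if (nrow(cond_rows) == 0)
      data.frame(month = integer(0), value = integer(0)) else {
      km <- data.frame(month = months_between(cond_rows$ref, dx_date),
                       value = as.integer(cond_rows$karnofsky))
      km <- km[km$month >= 0 & !is.na(km$value), , drop = FALSE]
      km <- km[!duplicated(km$month, fromLast = TRUE), , drop = FALSE]
      km[order(km$month), , drop = FALSE]
    }
    ddates <- c(dx_date, unlist(lapply(ths, function(t)
      lookup_val(ix, "end_date", t))), unlist(lapply(crs, function(cc)
        lookup_val(ix, "date", cc))))
    all_dates <- c(all_dates, ddates)
    diagnoses[[d]] <- list(
      diagnosis = d,
      pathology = iri_local(unname(ix$type_of[
        lookup_objs(ix, "hasPathologicalStructure", d)[1]]), ns),
      icd10 = lookup_val(ix, "icd10_code", d),
      date = dx_date,
      therapy_months = therapy_months,
      course_months = course_months,
      karnofsky = karnofsky)
  }
  all_dates <- c(all_dates, cond_rows$ref)
  last_enc <- if (length(all_dates) == 0) NA_character_ else
    max(all_dates, na.rm = TRUE)
  for (d in names(diagnoses)) diagnoses[[d]]$last_encounter <- last_enc
  structure(list(patient = patient, diagnoses = diagnoses,
                 last_encounter = last_enc),
            class = "patient_timeline")
}

#' @export
print.patient_timeline <- function(x, ...) {
  cat("<patient_timeline> ", x$patient, ": ", length(x$diagnoses),
      " diagnosis timeline(s), last encounter ", x$last_encounter, "\n",
      sep = "")
  invisible(x)
}

# Per-patient (month, category) event set for aggregation; categories are
# therapy classes and course kinds.
timeline_events <- function(tl, pathology_classes = NULL) {
  evs <- list()
  for (d in tl$diagnoses) {
    if (!is.null(pathology_classes) &&
        (is.na(d$pathology) || !d$pathology %in% pathology_classes)) next
    if (nrow(d$therapy_months) > 0)
      evs[[length(evs) + 1L]] <- data.frame(month = d$therapy_months$month,
                                            category = d$therapy_months$class,
                                            stringsAsFactors = FALSE)
    if (nrow(d$course_months) > 0)
      evs[[length(evs) + 1L]] <- data.frame(month = d$course_months$month,
                                            category = d$course_months$kind,
                                            stringsAsFactors = FALSE)
  }
  if (length(evs) == 0)
    return(data.frame(month = integer(0), category = character(0)))
  unique(do.call(rbind, evs))
}

#' Aggregate the timelines of a patient group into a month x category matrix
#'
#' Builds the timeline of every group member and counts, for each month of
#' the disease and each event category (therapy class or course kind), how
#' many patients show that event in that month.
#'
#' @param store a `semantic_store`
#' @param group character vector of patient IRIs (e.g. a [run_query()]
#'   result); must be non-empty
#' @param diagnosis optional pathological-structure class local name (e.g.
#'   `"Colorectal_cancer"`); expanded to its subclass closure. Only matching
#'   diagnoses contribute events.
#' @return an object of class `timeline_matrix`: integer matrix
#'   `counts` (months x categories), `months`, `categories`, `group`,
#'   `diagnosis`, `empty` flag
#' @export
aggregate_timelines <- function(store, group, diagnosis = NULL) {
  stopifnot(inherits(store, "semantic_store"))
  if (length(group) == 0)
    stop_odsreg("validation", "patient group is empty")
  ix <- store_index(store)
  path_classes <- NULL
  if (!is.null(diagnosis)) {
    path_classes <- iri_local(
      subclass_closure(store$ontology, iri_expand(diagnosis, store$namespace)),
      store$namespace)
  }
  per_patient <- lapply(sort_c(unique(group)), function(p) {
    tl <- build_timeline(store, p, index = ix)
    ev <- timeline_events(tl, path_classes)
    if (nrow(ev) > 0) ev$patient <- p
    ev
  })
  per_patient <- per_patient[vapply(per_patient, nrow, integer(1)) > 0]
  build_matrix(per_patient, group, diagnosis)
}

build_matrix <- function(per_patient, group, diagnosis) {
  if (length(per_patient) == 0) {
    counts <- matrix(0L, nrow = 0, ncol = 0)
    return(structure(list(counts = counts, months = integer(0),
                          categories = character(0),
                          group = sort_c(unique(group)),
                          diagnosis = diagnosis, empty = TRUE),
                     class = "timeline_matrix"))
  }
  ev <- do.call(rbind, per_patient)
  months <- 0:max(ev$month)
  categories <- sort_c(unique(ev$category))
  counts <- matrix(0L, nrow = length(months), ncol = length(categories),
                   dimnames = list(month = as.character(months),
                                   category = categories))
  tab <- table(factor(ev$month, levels = months),
               factor(ev$category, levels = categories))
  counts[] <- as.integer(tab)
  structure(list(counts = counts, months = months, categories = categories,
                 group = sort_c(unique(group)), diagnosis = diagnosis,
                 empty = FALSE),
            class = "timeline_matrix")
}

#' @export
print.timeline_matrix <- function(x, ...) {
  cat("<timeline_matrix> ", length(x$group), " patients, months 0..",
      if (length(x$months) > 0) max(x$months) else 0, ", ",
      length(x$categories), " categories",
      if (x$empty) " (empty)", "\n", sep = "")
  invisible(x)
}

#' Re-filter an aggregated timeline matrix by an event condition
#'
#' Recomputes the matrix over the subgroup of patients whose timeline
#' satisfies the condition: either "category active or occurring at a given
#' month", or "first therapy is the category" (`first_therapy = TRUE`, the
#' exploratory-therapy-simulator filter). A condition matched by no patient
#' yields a zero matrix flagged `empty`.
#'
#' @param store the `semantic_store` the matrix came from
#' @param matrix a `timeline_matrix`
#' @param category event category (therapy class or course kind local name)
#' @param month month index for the at-month condition (default 0)
#' @param first_therapy if TRUE, select patients whose earliest therapy
#'   month (within the matrix's diagnosis filter) includes `category`
#' @return a new `timeline_matrix` over the satisfying subgroup
#' @export
refilter_matrix <- function(store, matrix, category, month = 0L,
                            first_therapy = FALSE) {
  stopifnot(inherits(matrix, "timeline_matrix"))
  ix <- store_index(store)
  path_classes <- NULL
  if (!is.null(matrix$diagnosis))
    path_classes <- iri_local(
      subclass_closure(store$ontology,
                       iri_expand(matrix$diagnosis, store$namespace)),
      store$namespace)
  keep <- vapply(matrix$group, function(p) {
    tl <- build_timeline(store, p, index = ix)
    if (first_therapy) {
      for (d in tl$diagnoses) {
        if (!is.null(path_classes) &&
            (is.na(d$pathology) || !d$pathology %in% path_classes)) next
        tm <- d$therapy_months
        if (nrow(tm) == 0) next
        m0 <- min(tm$month)
        if (category %in% tm$class[tm$month == m0]) return(TRUE)
      }
      return(FALSE)
    }
    ev <- timeline_events(tl, path_classes)
    any(ev$month == month & ev$category == category)
  }, logical(1))
  sub <- matrix$group[keep]
  if (length(sub) == 0) {
    out <- matrix
    out$counts[] <- 0L
    out$empty <- TRUE
    out$group <- character(0)
    return(out)
  }
  aggregate_timelines(store, sub, diagnosis = matrix$diagnosis)
}

#' Export a timeline matrix in long format
#' @param matrix a `timeline_matrix`
#' @return data.frame(month, category, count)
#' @export
matrix_long <- function(matrix) {
  if (matrix$empty || length(matrix$months) == 0)
    return(data.frame(month = integer(0), category = character(0),
                      count = integer(0)))
  data.frame(month = rep(matrix$months, times = length(matrix$categories)),
             category = rep(matrix$categories, each = length(matrix$months)),
             count = as.integer(matrix$counts),
             stringsAsFactors = FALSE)
}
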