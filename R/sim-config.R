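# Simulation configuration: stratified probability stacks.

make_age_labels <- function(width = 5L, max_bin = 85L) {
  lo <- seq(0L, max_bin - width, by = width)
  c(paste0(lo, "-", lo + width - 1L), paste0(max_bin, "+"))
}

parse_age_label <- function(label, max_open_age = 99L) {
  if (grepl("\\+$", label)) {
    lo <- as.integer(sub("\\+$", "", label))
    return(c(lo, max_open_age))
  }
  parts <- as.integer(strsplit(label, "-", fixed = TRUE)[[1]])
  c(parts[1], parts[2])
}

# Normalise a weight vector: reject negatives, renormalise when the total is
# within 1% of one, otherwise reject.
normalise_weights <- function(w, what) {
  if (any(w < 0))
    stop_odsreg("validation", "negative weight in %s", what)
  s <- sum(w)
  if (abs(s - 1) > 0.01)
    stop_odsreg("validation", "weights in %s sum to %.4f (must be 1 within 1%%)",
                what, s)
  w / s
}

weight_table <- function(pairs, what) {
  cat_ <- vapply(pairs, function(p) as.character(p[[1]]), character(1))
  w <- vapply(pairs, function(p) as.numeric(p[[2]]), numeric(1))
  if (anyDuplicated(cat_))
    stop_odsreg("validation", "duplicate category in %s", what)
  w <- normalise_weights(w, what)
  data.frame(category = cat_, weight = w, cum = cumsum(w),
             stringsAsFactors = FALSE)
}

#' Load a simulation configuration into a distribution stack
#'
#' Parses the YAML configuration describing the stacked probability
#' distributions that drive the cohort simulator: per-stratum diagnosis
#' weights, per-diagnosis therapy weights, ICD-10 code stacks, the monthly
#' disease-course transition model, and the multi-diagnosis fraction.
#'
#' Weight lists are renormalised when their total is within 1% of one and
#' rejected otherwise; negative weights, therapy classes unknown to the
#' ontology, and stratum labels that do not correspond to a 5-year age bin
#' are validation errors.
#'
#' @param path YAML config; defaults to the shipped configuration
#' @param ontology an `ontology_model` to validate therapy/cancer classes
#'   against (default: the shipped ontology)
#' @return an object of class `distribution_stack`
#' @export
load_sim_config <- function(path = ods_example("sim-config.yaml"),
                            ontology = load_ontology()) {
  cfg <- yaml::read_yaml(path)
  width <- as.integer(cfg$age_bin_width %||% 5L)
  max_bin <- as.integer(cfg$max_age_bin %||% 85L)
  labels <- make_age_labels(width, max_bin)
  ns <- cfg$namespace %||% DEFAULT_NS

  check_label <- function(lbl, where) {
    bad <- setdiff(setdiff(lbl, "default"), labels)
    if (length(bad) > 0)
      stop_odsreg("validation", "%s keyed by unknown age stratum: %s",
                  where, paste(bad, collapse = ", "))
  }

  therapy_classes <- iri_local(subclass_closure(ontology, ods_iri("Therapy", ns)), ns)
  cancer_classes <- iri_local(
    subclass_closure(ontology, ods_iri("Pathological_structure", ns)), ns)
  course_classes <- iri_local(
    subclass_closure(ontology, ods_iri("Disease_course", ns)), ns)

  check_label(names(cfg$diagnosis_weights), "diagnosis_weights")
  diagnosis <- lapply(cfg$diagnosis_weights, weight_table, what = "diagnosis_weights")
  for (tab in diagnosis) {
    unknown <- setdiff(tab$category, cancer_classes)
    if (length(unknown) > 0)
      stop_odsreg("validation", "unknown cancer class in diagnosis_weights: %s",
                  paste(unknown, collapse = ", "))
  }
  if (!"default" %in% names(diagnosis))
    stop_odsreg("validation", "diagnosis_weights needs a 'default' table")

  check_label(names(cfg$therapy_weights), "therapy_weights")
  therapy <- lapply(cfg$therapy_weights, function(per_dx)
    lapply(per_dx, weight_table, what = "therapy_weights"))
  for (per_dx in therapy) for (tab in per_dx) {
    unknown <- setdiff(tab$category, therapy_classes)
    if (length(unknown) > 0)
      stop_odsreg("validation", "unknown therapy class: %s",
                  paste(unknown, collapse = ", "))
  }
  if (!"default" %in% names(therapy))
    stop_odsreg("validation", "therapy_weights needs a 'default' block")

  catalog <- lapply(cfg$diagnosis_catalog, function(entry) {
    list(anatomical_structure = entry$anatomical_structure %||% "",
         tumor_type = entry$tumor_type %||% "",
         icd10 = lapply(entry$icd10_codes, weight_table, what = "icd10_codes"))
  })

  cm <- cfg$course_model
  states <- as.character(cm$states)
  unknown <- setdiff(states, course_classes)
  if (length(unknown) > 0)
    stop_odsreg("validation", "unknown course kind: %s",
                paste(unknown, collapse = ", "))
  absorbing <- as.character(cm$absorbing)
  initial <- unlist(cm$initial)
  initial <- normalise_weights(initial, "course initial distribution")
  transitions <- lapply(cm$transitions, function(per_state) {
    lapply(per_state, function(row) {
      w <- unlist(row)
      unknown <- setdiff(names(w), states)
      if (length(unknown) > 0)
        stop_odsreg("validation", "transition to unknown state: %s",
                    paste(unknown, collapse = ", "))
      w <- normalise_weights(w, "course transition row")
      cumsum(w)
    })
  })
  if (!"default" %in% names(transitions))
    stop_odsreg("validation", "course transitions need a 'default' table")

  multidx <- cfg$multidx_fraction %||% list(default = 0)
  check_label(names(multidx), "multidx_fraction")

  stratum_w <- unlist(cfg$stratum_weights %||%
                        stats::setNames(rep(1 / length(labels), length(labels)),
                                        labels))
  check_label(names(stratum_w), "stratum_weights")
  stratum_w <- normalise_weights(stratum_w, "stratum_weights")
  gender_w <- unlist(cfg$gender_weights %||% c(M = 0.5, F = 0.5))
  gender_w <- normalise_weights(gender_w, "gender_weights")

  genders <- names(gender_w)
  bounds <- t(vapply(labels, parse_age_label, integer(2)))
  strata <- do.call(rbind, lapply(genders, function(g)
    data.frame(key = paste0(g, "|", labels), gender = g, label = labels,
               age_lo = bounds[, 1], age_hi = bounds[, 2],
               stringsAsFactors = FALSE)))
  rownames(strata) <- NULL

  out <- structure(list(
    namespace = ns,
    labels = labels,
    strata = strata,
    diagnosis = diagnosis,
    therapy = therapy,
    catalog = catalog,
    course = list(states = states, absorbing = absorbing,
                  initial = cumsum(initial), transitions = transitions),
    multidx = multidx,
    stratum_weights = stratum_w,
    gender_weights = gender_w,
    params = list(
      index_date = as.Date(cfg$index_date %||% "2010-01-01"),
      therapy_continue_prob = cfg$therapy_continue_prob %||% 0.5,
      max_therapies = as.integer(cfg$max_therapies %||% 6L),
      therapy_duration_months = as.integer(cfg$therapy_duration_months %||% c(1L, 3L)),
      max_course_months = as.integer(cfg$max_course_months %||% 60L)
    ),
    condition_model = cfg$condition_model
  ), class = "distribution_stack")
  out <- structure(c(unclass(out), list(compiled = compile_stack(out))),
                   class = "distribution_stack")
  out
}

# Lookup helpers with 'default' fallback.
stack_diagnosis_table <- function(stack, label) {
  stack$diagnosis[[label]] %||% stack$diagnosis[["default"]]
}

stack_therapy_table <- function(stack, label, diagnosis) {
  per_dx <- stack$therapy[[label]] %||% stack$therapy[["default"]]
  tab <- per_dx[[diagnosis]] %||% stack$therapy[["default"]][[diagnosis]]
  if (is.null(tab))
    stop_odsreg("validation", "no therapy weights for diagnosis %s", diagnosis)
  tab
}

stack_multidx <- function(stack, label) {
  as.numeric(stack$multidx[[label]] %||% stack$multidx[["default"]] %||% 0)
}

stack_transitions <- function(stack, diagnosis) {
  stack$course$transitions[[diagnosis]] %||% stack$course$transitions[["default"]]
}

stack_icd_table <- function(stack, diagnosis, gender) {
  entry <- stack$catalog[[diagnosis]]
  if (is.null(entry))
    stop_odsreg("validation", "no catalog entry for diagnosis %s", diagnosis)
  entry$icd10[[gender]] %||% entry$icd10[["default"]]
}

#' @export
print.distribution_stack <- function(x, ...) {
  cat("<distribution_stack> ", nrow(x$strata), " strata (",
      paste(names(x$gender_weights), collapse = "/"), " x ",
      length(x$labels), " age bins), ",
      length(x$catalog), " diagnosis categories\n", sep = "")
  invisible(x)
}

#' Sample from a cumulative categorical stack
#'
#' Maps uniform draws onto categories through the stacked cumulative
#' boundaries: category *i* covers the half-open interval
#' `[cum[i-1], cum[i])`. This is the elementary operation of the simulator:
#' a random number falling in a category's band selects that category.
#'
#' @param cum_weights named non-decreasing numeric vector of cumulative
#'   boundaries; the last boundary must be 1 (within 1e-9)
#' @param u numeric vector of uniform draws in `[0, 1)`
#' @return character vector of category names, one per draw
#' @examples
#' cum <- cumsum(c(breast = 0.23, lung = 0.17, prostate = 0.17,
#'                 colorectal = 0.08, other = 0.35))
#' sample_categorical(cum, 0.60)  # falls in the colorectal band
#' @export
sample_categorical <- function(cum_weights, u) {
  if (is.unsorted(cum_weights))
    stop_odsreg("validation", "cumulative boundaries must be non-decreasing")
  if (abs(cum_weights[[length(cum_weights)]] - 1) > 1e-9)
    stop_odsreg("validation", "last cumulative boundary must be 1")
  if (any(u < 0 | u >= 1))
    stop_odsreg("validation", "u must lie in [0, 1)")
  idx <- findInterval(u, cum_weights) + 1L
  idx[idx > length(cum_weights)] <- length(cum_weights)
  names(cum_weights)[idx]
}

# Internal: unchecked draw from a precompiled named cumulative vector.
fast_draw <- function(cum, u) {
  idx <- findInterval(u, cum) + 1L
  if (idx > length(cum)) idx <- length(cum)
  names(cum)[idx]
}

# Internal: one categorical draw from a weight_table data.frame.
draw_cat <- function(tab) {
  cum <- stats::setNames(tab$cum, tab$category)
  cum[length(cum)] <- 1  # guard against numeric drift in the last boundary
  fast_draw(cum, stats::runif(1))
}

# Precompile the stack's weight tables into named cumulative vectors for the
# simulator's hot path.
compile_stack <- function(stack) {
  as_cum <- function(tab) {
    cum <- stats::setNames(tab$cum, tab$category)
    cum[length(cum)] <- 1
    cum
  }
  comp <- list()
  comp$diag <- lapply(stack$diagnosis, as_cum)
  comp$ther <- lapply(stack$therapy, function(per_dx) lapply(per_dx, as_cum))
  comp$icd <- lapply(stack$catalog, function(entry) lapply(entry$icd10, as_cum))
  comp$initial <- stack$course$initial
  comp
}
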