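# Stratified cohort simulator: gender x 5-year age strata -> diagnosis stack
# -> therapy stack per diagnosis -> monthly disease-course chain, with a
# controlled multi-diagnosis fraction.
#
# Rows are accumulated column-wise in pre-allocated atomic vectors (IDs are
# sequential and generated at the end); this keeps a 20k-patient run free of
# per-row allocation churn.

# Small fixed stacks for staging/grading attributes (documented in the
# methods vignette; they only add attribute diversity, no downstream weight).
GRADING_CUM <- cumsum(c(G1 = 0.20, G2 = 0.35, G3 = 0.30, G4 = 0.15))
TNM_T_CUM <- cumsum(c(T1 = 0.25, T2 = 0.35, T3 = 0.25, T4 = 0.15))
TNM_N_CUM <- cumsum(c(N0 = 0.50, N1 = 0.30, N2 = 0.20))
TNM_M_CUM <- cumsum(c(M0 = 0.80, M1 = 0.20))
STAGE_CUM <- cumsum(c(I = 0.30, II = 0.30, III = 0.25, IV = 0.15))
MEDICATIONS <- c("5-FU", "capecitabine", "cisplatin", "docetaxel",
                 "doxorubicin", "oxaliplatin", "paclitaxel", "tamoxifen")

SIM_COLS <- list(
  p = c(gender = "character", birth = "integer"),
  c = c(pidx = "integer", ref = "integer", age = "integer",
        weight = "numeric", height = "numeric", karnofsky = "integer",
        asa = "integer", menopause = "character"),
  d = c(pidx = "integer", icd = "character", grading = "character",
        tnm_t = "character", tnm_n = "character", tnm_m = "character",
        date = "integer", path = "character", anat = "character",
        tumor = "character"),
  t = c(didx = "integer", class = "character", med = "character",
        start = "integer", end = "integer"),
  o = c(didx = "integer", kind = "character", stage = "character",
        ord = "integer", date = "integer"),
  y = c(stratum = "character", pidx = "integer", diagnosis = "character",
        first_therapy = "character", multi = "logical")
)

new_sim_env <- function(cap = 1024L) {
  e <- new.env(parent = emptyenv())
  for (tb in names(SIM_COLS)) {
    e[[paste0("n_", tb)]] <- 0L
    for (col in names(SIM_COLS[[tb]]))
      e[[paste0(tb, "_", col)]] <- vector(SIM_COLS[[tb]][[col]], cap)
  }
  e
}

# Geometric growth of a table's column vectors; amortised O(1) appends.
grow_tab <- function(env, tb, n) {
  for (col in names(SIM_COLS[[tb]])) {
    f <- paste0(tb, "_", col)
    if (n > length(env[[f]])) length(env[[f]]) <- 2L * n
  }
}

fmt_id <- function(prefix, i) sprintf("%s%06d", prefix, i)

# Simulate one patient into the accumulator environment. Dates are integer
# epoch days throughout; finish_registry() converts them to ISO strings.
sim_one <- function(stack, gender, label, env) {
  p <- stack$params
  comp <- stack$compiled
  runif <- stats::runif
  bounds <- parse_age_label(label)
  age <- if (bounds[1] == bounds[2]) bounds[1] else
    bounds[1] + floor(runif(1) * (bounds[2] - bounds[1] + 1))
  dx1_date <- as.integer(p$index_date) + (floor(runif(1) * 1461L) - 730L)
  birth_date <- as.integer(dx1_date - ceiling(age * 365.25) - floor(runif(1) * 365))

  ip <- env$n_p + 1L
  env$n_p <- ip
  if (ip > length(env$p_gender)) grow_tab(env, "p", ip)
  env$p_gender[ip] <- gender
  env$p_birth[ip] <- birth_date

  multi <- runif(1) < stack_multidx(stack, label)
  ndx <- if (multi) 2L else 1L
  diag_cum <- comp$diag[[label]] %||% comp$diag[["default"]]
  kbase <- c(90L, 100L)[1L + (runif(1) < 0.5)]
  cmod <- stack$condition_model
  wpar <- unlist(cmod$weight_kg[[gender]]) %||% c(75, 12)
  hpar <- unlist(cmod$height_cm[[gender]]) %||% c(170, 8)
  weight0 <- round(stats::rnorm(1, wpar[1], wpar[2]), 1)
  height0 <- round(stats::rnorm(1, hpar[1], hpar[2]), 1)
  asa_w <- unlist(cmod$asa_weights) %||% rep(1 / 6, 6)
  asa <- as.integer(fast_draw(
    stats::setNames(cumsum(asa_w / sum(asa_w)), as.character(1:6)), runif(1)))
  menopause <- if (gender == "F") {
    if (age >= 50) "postmenopausal" else "premenopausal"
  } else ""

  emit_condition <- function(ref_date, months_after, karnofsky) {
    i <- env$n_c + 1L
    env$n_c <- i
    if (i > length(env$c_pidx)) grow_tab(env, "c", i)
    env$c_pidx[i] <- ip
    env$c_ref[i] <- ref_date
    env$c_age[i] <- age + (months_after %/% 12L)
    env$c_weight[i] <- weight0
    env$c_height[i] <- height0
    env$c_karnofsky[i] <- karnofsky
    env$c_asa[i] <- asa
    env$c_menopause[i] <- menopause
  }

  ther_per_label <- comp$ther[[label]] %||% comp$ther[["default"]]
  chosen <- character(0)
  for (j in seq_len(ndx)) {
    cum <- diag_cum
    if (j > 1L) {
      keep <- !names(cum) %in% chosen
      if (!any(keep)) break
      w <- diff(c(0, cum))[keep]
      cum <- stats::setNames(cumsum(w / sum(w)), names(cum)[keep])
      cum[length(cum)] <- 1
    }
    dx_cat <- fast_draw(cum, runif(1))
    chosen <- c(chosen, dx_cat)
    dx_date <- if (j == 1L) dx1_date else
      add_months_int(dx1_date, 1L + floor(runif(1) * 36))

    cat_entry <- stack$catalog[[dx_cat]]
    icd_cum <- comp$icd[[dx_cat]][[gender]] %||% comp$icd[[dx_cat]][["default"]]
    id <- env$n_d + 1L
    env$n_d <- id
    if (id > length(env$d_pidx)) grow_tab(env, "d", id)
    env$d_pidx[id] <- ip
    env$d_icd[id] <- fast_draw(icd_cum, runif(1))
    env$d_grading[id] <- fast_draw(GRADING_CUM, runif(1))
    env$d_tnm_t[id] <- fast_draw(TNM_T_CUM, runif(1))
    env$d_tnm_n[id] <- fast_draw(TNM_N_CUM, runif(1))
    env$d_tnm_m[id] <- fast_draw(TNM_M_CUM, runif(1))
    env$d_date[id] <- dx_date
    env$d_path[id] <- dx_cat
    env$d_anat[id] <- cat_entry$anatomical_structure %||% ""
    env$d_tumor[id] <- cat_entry$tumor_type %||% ""

    # therapies: geometric stopping rule, months laid out contiguously
    ther_cum <- ther_per_label[[dx_cat]] %||% comp$ther[["default"]][[dx_cat]]
    if (is.null(ther_cum))
      stop_odsreg("validation", "no therapy weights for diagnosis %s", dx_cat)
    nther <- 1L
    while (nther < p$max_therapies &&
           runif(1) < p$therapy_continue_prob) nther <- nther + 1L
    moff <- 0L
    first_therapy <- NA_character_
    dmin <- p$therapy_duration_months[1]
    dmax <- p$therapy_duration_months[2]
    for (t in seq_len(nther)) {
      tcl <- fast_draw(ther_cum, runif(1))
      if (t == 1L) first_therapy <- tcl
      dur <- dmin + floor(runif(1) * (dmax - dmin + 1L))
      it <- env$n_t + 1L
      env$n_t <- it
      if (it > length(env$t_didx)) grow_tab(env, "t", it)
      env$t_didx[it] <- id
      env$t_class[it] <- tcl
      env$t_med[it] <- if (grepl("hemo|rug|ormon|mmuno", tcl))
        MEDICATIONS[1L + floor(runif(1) * length(MEDICATIONS))] else ""
      env$t_start[it] <- add_months_int(dx_date, moff)
      env$t_end[it] <- add_months_int(dx_date, moff + dur - 1L)
      moff <- moff + dur
    }

    # monthly course chain until absorption or max_course_months
    stage <- fast_draw(STAGE_CUM, runif(1))
    trans <- stack_transitions(stack, dx_cat)
    state <- fast_draw(comp$initial, runif(1))
    karnofsky <- kbase
    ord <- 1L
    emit_course <- function(kind, ord, date) {
      i <- env$n_o + 1L
      env$n_o <- i
      if (i > length(env$o_didx)) grow_tab(env, "o", i)
      env$o_didx[i] <- id
      env$o_kind[i] <- kind
      env$o_stage[i] <- stage
      env$o_ord[i] <- ord
      env$o_date[i] <- date
    }
    emit_course(state, ord, dx_date)
    emit_condition(dx_date, 0L, karnofsky)
    if (!state %in% stack$course$absorbing) {
      for (m in seq_len(p$max_course_months)) {
        nxt <- fast_draw(trans[[state]], runif(1))
        if (nxt != state) {
          karnofsky <- switch(nxt,
            Progression = karnofsky - 10L,
            Recurrence = karnofsky - 10L,
            Complete_remission = min(karnofsky + 10L, 100L),
            Death = 0L,
            karnofsky)
          karnofsky <- max(0L, min(100L, karnofsky))
          ord <- ord + 1L
          d <- add_months_int(dx_date, m)
          emit_course(nxt, ord, d)
          emit_condition(d, m, karnofsky)
          state <- nxt
          if (state %in% stack$course$absorbing) break
        }
      }
    }

    iy <- env$n_y + 1L
    env$n_y <- iy
    if (iy > length(env$y_pidx)) grow_tab(env, "y", iy)
    env$y_stratum[iy] <- paste0(gender, "|", label)
    env$y_pidx[iy] <- ip
    env$y_diagnosis[iy] <- dx_cat
    env$y_first_therapy[iy] <- first_therapy
    env$y_multi[iy] <- multi
  }
  invisible(NULL)
}

col_of <- function(env, tb, col, n) env[[paste0(tb, "_", col)]][seq_len(n)]

iso_date <- function(x) as.character(as.Date(x, origin = "1970-01-01"))

ZERO_OFFSETS <- list(p = 0L, c = 0L, d = 0L, t = 0L, o = 0L)

# Materialise one accumulator environment into registry tables plus the
# per-diagnosis tally; `off` carries the ID offsets of earlier chunks.
collect_chunk <- function(env, off = ZERO_OFFSETS) {
  np <- env$n_p; nc <- env$n_c; nd <- env$n_d; nt <- env$n_t; no <- env$n_o
  pid <- fmt_id("P", off$p + seq_len(np))
  did <- fmt_id("D", off$d + seq_len(nd))
  patients <- data.frame(
    patient_id = pid,
    gender = col_of(env, "p", "gender", np),
    birth_date = iso_date(col_of(env, "p", "birth", np)),
    stringsAsFactors = FALSE)
  conditions <- data.frame(
    condition_id = fmt_id("PC", off$c + seq_len(nc)),
    patient_id = pid[col_of(env, "c", "pidx", nc)],
    ref_date = iso_date(col_of(env, "c", "ref", nc)),
    age = col_of(env, "c", "age", nc),
    weight_kg = col_of(env, "c", "weight", nc),
    height_cm = col_of(env, "c", "height", nc),
    karnofsky = col_of(env, "c", "karnofsky", nc),
    asa = col_of(env, "c", "asa", nc),
    menopause_status = col_of(env, "c", "menopause", nc),
    stringsAsFactors = FALSE)
  diagnoses <- data.frame(
    diagnosis_id = did,
    patient_id = pid[col_of(env, "d", "pidx", nd)],
    icd10_code = col_of(env, "d", "icd", nd),
    grading = col_of(env, "d", "grading", nd),
    tnm_t = col_of(env, "d", "tnm_t", nd),
    tnm_n = col_of(env, "d", "tnm_n", nd),
    tnm_m = col_of(env, "d", "tnm_m", nd),
    date = iso_date(col_of(env, "d", "date", nd)),
    pathological_structure = col_of(env, "d", "path", nd),
    anatomical_structure = col_of(env, "d", "anat", nd),
    tumor_type = col_of(env, "d", "tumor", nd),
    stringsAsFactors = FALSE)
  therapies <- data.frame(
    therapy_id = fmt_id("T", off$t + seq_len(nt)),
    diagnosis_id = did[col_of(env, "t", "didx", nt)],
    therapy_class = col_of(env, "t", "class", nt),
    medication = col_of(env, "t", "med", nt),
    start_date = iso_date(col_of(env, "t", "start", nt)),
    end_date = iso_date(col_of(env, "t", "end", nt)),
    stringsAsFactors = FALSE)
  courses <- data.frame(
    course_id = fmt_id("C", off$o + seq_len(no)),
    diagnosis_id = did[col_of(env, "o", "didx", no)],
    course_kind = col_of(env, "o", "kind", no),
    stage = col_of(env, "o", "stage", no),
    order = col_of(env, "o", "ord", no),
    date = iso_date(col_of(env, "o", "date", no)),
    stringsAsFactors = FALSE)

  ny <- env$n_y
  tally <- data.frame(
    stratum = col_of(env, "y", "stratum", ny),
    patient_id = pid[col_of(env, "y", "pidx", ny)],
    diagnosis = col_of(env, "y", "diagnosis", ny),
    first_therapy = col_of(env, "y", "first_therapy", ny),
    multi = col_of(env, "y", "multi", ny),
    stringsAsFactors = FALSE)
  list(patients = patients, conditions = conditions, diagnoses = diagnoses,
       therapies = therapies, courses = courses, tally = tally)
}

make_summary <- function(tally, np, nd) {
  if (nrow(tally) == 0)
    return(list(n_patients = 0L, n_diagnoses = 0L,
                multidx_fraction = NA_real_, per_stratum = list()))
  per_stratum <- lapply(split(tally, tally$stratum), function(d) {
    list(n_diagnoses = nrow(d),
         diagnosis_freq = as.list(table(d$diagnosis) / nrow(d)),
         first_therapy_freq = lapply(
           split(d, d$diagnosis),
           function(dd) as.list(table(dd$first_therapy) / nrow(dd))))
  })
  list(n_patients = np, n_diagnoses = nd,
       multidx_fraction = mean(tapply(tally$multi, tally$patient_id, any)),
       per_stratum = per_stratum)
}

finish_registry <- function(env) {
  ch <- collect_chunk(env)
  reg <- ch[REGISTRY_TABLES]
  reg$summary <- make_summary(ch$tally, env$n_p, env$n_d)
  structure(reg, class = "registry")
}

#' Simulate a single patient record bundle
#'
#' Draws one patient from a stratum: diagnosis count from the configured
#' multi-diagnosis fraction, each diagnosis from the stratum's diagnosis
#' stack, one or more therapies sampled sequentially from the per-diagnosis
#' therapy stack with month-contiguous dates, and a disease-course sequence
#' from the monthly transition chain until absorption. Uses the current RNG
#' state; seed with [set.seed()] for reproducibility.
#'
#' @param stack a `distribution_stack` from [load_sim_config()]
#' @param gender `"M"` or `"F"`
#' @param age_label age stratum label such as `"60-64"`
#' @return a `registry` object holding the generated rows for this patient
#' @export
simulate_patient <- function(stack, gender = "M", age_label = "60-64") {
  stopifnot(inherits(stack, "distribution_stack"))
  if (!age_label %in% stack$labels)
    stop_odsreg("validation", "unknown age stratum: %s", age_label)
  env <- new_sim_env(cap = 64L)
  sim_one(stack, gender, age_label, env)
  finish_registry(env)
}

#' Simulate a synthetic cancer-registry cohort
#'
#' Generates `n` patients by (1) assigning each to a gender x age stratum,
#' (2) walking the stacked probability distributions of the configuration
#' (diagnosis weights per stratum, therapy weights per diagnosis, monthly
#' course transitions), and (3) emitting relational-style rows for patients,
#' patient conditions, diagnoses, therapies and disease courses. A summary
#' report with per-stratum empirical frequencies is attached.
#'
#' @param stack a `distribution_stack`
#' @param n number of patients (>= 1)
#' @param stratum_weights optional named weights over strata; names are
#'   either age labels (`"60-64"`, split across genders by the configured
#'   gender weights) or full keys (`"M|60-64"`). Default: the configuration's
#'   stratum and gender weights.
#' @param seed optional integer seed (sets the RNG before sampling)
#' @return a `registry` object: data.frames `patients`, `conditions`,
#'   `diagnoses`, `therapies`, `courses`, plus `summary`
#' @examples
#' stack <- load_sim_config()
#' reg <- simulate_cohort(stack, n = 50, seed = 1)
#' nrow(reg$patients)
#' @export
simulate_cohort <- function(stack, n, stratum_weights = NULL, seed = NULL) {
  stopifnot(inherits(stack, "distribution_stack"))
  if (!is.numeric(n) || n < 1)
    stop_odsreg("validation", "n must be >= 1")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(as.integer(seed))

  if (is.null(stratum_weights)) {
    w <- as.vector(outer(stack$gender_weights, stack$stratum_weights))
    keys <- as.vector(outer(names(stack$gender_weights),
                            names(stack$stratum_weights), paste, sep = "|"))
  } else {
    nm <- names(stratum_weights)
    if (is.null(nm)) stop_odsreg("validation", "stratum_weights must be named")
    if (all(nm %in% stack$labels)) {
      keys <- as.vector(outer(names(stack$gender_weights), nm, paste, sep = "|"))
      w <- as.vector(outer(stack$gender_weights, stratum_weights))
    } else {
      keys <- nm
      w <- as.numeric(stratum_weights)
      bad <- setdiff(keys, stack$strata$key)
      if (length(bad) > 0)
        stop_odsreg("validation", "unknown stratum key: %s",
                    paste(bad, collapse = ", "))
    }
  }
  w <- w / sum(w)
  assigned <- sample(keys, n, replace = TRUE, prob = w)
  parts <- strsplit(assigned, "|", fixed = TRUE)

  # chunked accumulation keeps the working set small and appends O(1)
  chunk_size <- 1000L
  off <- ZERO_OFFSETS
  chunks <- vector("list", ceiling(n / chunk_size))
  for (k in seq_along(chunks)) {
    lo <- (k - 1L) * chunk_size + 1L
    hi <- min(k * chunk_size, n)
    env <- new_sim_env(cap = 2L * chunk_size)
    for (i in lo:hi)
      sim_one(stack, parts[[i]][1], parts[[i]][2], env)
    chunks[[k]] <- collect_chunk(env, off)
    off <- list(p = off$p + env$n_p, c = off$c + env$n_c, d = off$d + env$n_d,
                t = off$t + env$n_t, o = off$o + env$n_o)
  }
  bind <- function(field) {
    df <- data.table::rbindlist(lapply(chunks, `[[`, field))
    data.table::setDF(df)
    df
  }
  reg <- lapply(stats::setNames(REGISTRY_TABLES, REGISTRY_TABLES), bind)
  reg$summary <- make_summary(bind("tally"), off$p, off$d)
  structure(reg, class = "registry")
}

#' @export
print.registry <- function(x, ...) {
  cat("<registry> ", nrow(x$patients), " patients, ",
      nrow(x$diagnoses), " diagnoses, ", nrow(x$therapies), " therapies, ",
      nrow(x$courses), " courses, ", nrow(x$conditions), " conditions\n",
      sep = "")
  invisible(x)
}

REGISTRY_TABLES <- c("patients", "conditions", "diagnoses", "therapies", "courses")

#' Write a registry to a directory of CSV files
#'
#' Emits `patients.csv`, `conditions.csv`, `diagnoses.csv`, `therapies.csv`,
#' `courses.csv` and a `summary.json` report.
#'
#' @param registry a `registry` object
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
write_registry <- function(registry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tb in REGISTRY_TABLES)
    utils::write.csv(registry[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE)
  if (!is.null(registry$summary))
    jsonlite::write_json(registry$summary, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a registry from a directory of CSV files
#' @param dir directory containing the five registry CSV files
#' @return a `registry` object
#' @export
read_registry <- function(dir) {
  reg <- lapply(stats::setNames(REGISTRY_TABLES, REGISTRY_TABLES), function(tb) {
    f <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(f)) stop_odsreg("validation", "missing table file: %s", f)
    utils::read.csv(f, stringsAsFactors = FALSE, colClasses = "character")
  })
  for (col in c("age", "weight_kg", "height_cm", "karnofsky", "asa"))
    reg$conditions[[col]] <- as.numeric(reg$conditions[[col]])
  reg$courses$order <- as.integer(reg$courses$order)
  structure(reg, class = "registry")
}

#' Validate the referential and temporal integrity of a registry
#'
#' Checks that all foreign keys resolve, therapy start <= end, diagnosis
#' dates are not before birth, and course `order` values per diagnosis are
#' consecutive from 1 and date-sorted.
#'
#' @param registry a `registry` object
#' @return list with `ok` (logical) and `problems` (character vector naming
#'   offending rows)
#' @export
validate_registry <- function(registry) {
  probs <- character(0)
  d <- registry
  bad <- !d$conditions$patient_id %in% d$patients$patient_id
  if (any(bad)) probs <- c(probs, paste0("condition ", d$conditions$condition_id[bad],
                                         ": dangling patient_id"))
  bad <- !d$diagnoses$patient_id %in% d$patients$patient_id
  if (any(bad)) probs <- c(probs, paste0("diagnosis ", d$diagnoses$diagnosis_id[bad],
                                         ": dangling patient_id"))
  bad <- !d$therapies$diagnosis_id %in% d$diagnoses$diagnosis_id
  if (any(bad)) probs <- c(probs, paste0("therapy ", d$therapies$therapy_id[bad],
                                         ": dangling diagnosis_id"))
  bad <- !d$courses$diagnosis_id %in% d$diagnoses$diagnosis_id
  if (any(bad)) probs <- c(probs, paste0("course ", d$courses$course_id[bad],
                                         ": dangling diagnosis_id"))
  bad <- as.Date(d$therapies$start_date) > as.Date(d$therapies$end_date)
  if (any(bad)) probs <- c(probs, paste0("therapy ", d$therapies$therapy_id[bad],
                                         ": start_date after end_date"))
  birth <- d$patients$birth_date[match(d$diagnoses$patient_id,
                                       d$patients$patient_id)]
  bad <- !is.na(birth) & as.Date(d$diagnoses$date) < as.Date(birth)
  if (any(bad)) probs <- c(probs, paste0("diagnosis ", d$diagnoses$diagnosis_id[bad],
                                         ": date before birth"))
  ord_split <- split(seq_len(nrow(d$courses)), d$courses$diagnosis_id)
  for (did in names(ord_split)) {
    idx <- ord_split[[did]]
    orda <- sort(as.integer(d$courses$order[idx]))
    if (!identical(orda, seq_along(idx)))
      probs <- c(probs, paste0("diagnosis ", did, ": course order not 1..K"))
    dates <- as.Date(d$courses$date[idx])[order(d$courses$order[idx])]
    if (is.unsorted(dates, strictly = TRUE))
      probs <- c(probs, paste0("diagnosis ", did, ": course dates not increasing"))
  }
  list(ok = length(probs) == 0, problems = probs)
}
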