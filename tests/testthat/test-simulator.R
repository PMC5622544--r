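# Simulation configuration and cohort generator.

test_that("the shipped configuration carries the published 60-64 stack", {
  stack <- shipped_stack()
  tab <- odsreg:::stack_diagnosis_table(stack, "60-64")
  w <- stats::setNames(tab$weight, tab$category)
  expect_equal(unname(w["Breast_cancer"]), 0.23)
  expect_equal(unname(w["Lung_cancer"]), 0.17)
  expect_equal(unname(w["Prostate_cancer"]), 0.17)
  expect_equal(unname(w["Colorectal_cancer"]), 0.08)
  tw <- odsreg:::stack_therapy_table(stack, "60-64", "Colorectal_cancer")
  tw <- stats::setNames(tw$weight, tw$category)
  expect_equal(unname(tw["Teletherapy"]), 0.44)
  expect_equal(unname(tw["Chemotherapy"]), 0.44)
  expect_equal(unname(tw["SurgicalTreatment"]), 0.12)
})

test_that("categorical stack sampling maps draws to cumulative bands", {
  stack <- shipped_stack()
  tab <- odsreg:::stack_diagnosis_table(stack, "60-64")
  cum <- stats::setNames(tab$cum, tab$category)
  # a draw of 0.60 falls in the colorectal band of the 60-64 stack
  expect_equal(sample_categorical(cum, 0.60), "Colorectal_cancer")
  # lower boundary belongs to the first category
  expect_equal(sample_categorical(cum, 0), "Breast_cancer")
  # half-open intervals: the exact boundary starts the next category
  expect_equal(sample_categorical(cum, cum[["Breast_cancer"]]), "Lung_cancer")
  expect_error(sample_categorical(cum, 1), class = "odsreg_validation_error")
  expect_error(sample_categorical(cum, -0.1), class = "odsreg_validation_error")
})

test_that("seeded draws recover the stack weights within 3 standard errors", {
  cum <- cumsum(c(a = 0.2, b = 0.3, c = 0.5))
  set.seed(2024)
  draws <- sample_categorical(cum, runif(10000))
  freq <- table(draws) / 10000
  for (cat in names(cum)) {
    w <- diff(c(0, cum))[[cat]]
    se <- sqrt(w * (1 - w) / 10000)
    expect_lt(abs(freq[[cat]] - w), 3 * se)
  }
})

test_that("config validation rejects bad weight tables", {
  # weights summing to 0.90 violate the 1% renormalisation bound
  expect_error(odsreg:::weight_table(list(list("A", 0.5), list("B", 0.4)), "x"),
               class = "odsreg_validation_error")
  expect_error(odsreg:::weight_table(list(list("A", -0.1), list("B", 1.1)), "x"),
               class = "odsreg_validation_error")
  # weights within 1% are renormalised to sum exactly 1
  tab <- odsreg:::weight_table(list(list("A", 0.501), list("B", 0.502)), "x")
  expect_equal(sum(tab$weight), 1)
  # unknown therapy class in the config is caught against the ontology
  cfg <- yaml::read_yaml(ods_example("sim-config.yaml"))
  cfg$therapy_weights$default$Melanoma[[1]][[1]] <- "NotATherapy"
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, tmp)
  expect_error(load_sim_config(tmp, ontology = shipped_ontology()),
               class = "odsreg_validation_error")
})

test_that("simulation is reproducible and referentially sound", {
  stack <- shipped_stack()
  r1 <- simulate_cohort(stack, 150, seed = 42)
  r2 <- simulate_cohort(stack, 150, seed = 42)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_registry(r1, d1); write_registry(r2, d2)
  for (tb in odsreg:::REGISTRY_TABLES)
    expect_identical(readLines(file.path(d1, paste0(tb, ".csv"))),
                     readLines(file.path(d2, paste0(tb, ".csv"))))
  v <- validate_registry(r1)
  expect_true(v$ok)
  expect_length(v$problems, 0)
  # CSV round-trip preserves the tables
  back <- read_registry(d1)
  expect_equal(back$patients, r1$patients)
  expect_equal(nrow(back$courses), nrow(r1$courses))
})

test_that("degenerate stacks force the configured outcome", {
  cfg <- yaml::read_yaml(ods_example("sim-config.yaml"))
  cfg$diagnosis_weights <- list(default = list(list("Colorectal_cancer", 1.0)))
  cfg$therapy_weights <- list(default = list(
    Colorectal_cancer = list(list("Chemotherapy", 1.0))))
  cfg$multidx_fraction <- list(default = 0)
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, tmp)
  stack <- load_sim_config(tmp, ontology = shipped_ontology())
  reg <- simulate_cohort(stack, 60, seed = 5)
  expect_true(all(reg$diagnoses$pathological_structure == "Colorectal_cancer"))
  expect_true(all(reg$therapies$therapy_class == "Chemotherapy"))
  # multi-diagnosis fraction 0: exactly one diagnosis per patient
  expect_equal(nrow(reg$diagnoses), nrow(reg$patients))
})

test_that("course sequences are ordered, dated and absorb correctly", {
  reg <- sim_registry(n = 120, seed = 101)
  absorbing <- c("Death", "Complete_remission")
  for (did in unique(reg$courses$diagnosis_id)) {
    cr <- reg$courses[reg$courses$diagnosis_id == did, ]
    cr <- cr[order(cr$order), ]
    expect_identical(as.integer(cr$order), seq_len(nrow(cr)))
    expect_false(is.unsorted(as.Date(cr$date), strictly = TRUE))
    hits <- which(cr$course_kind %in% absorbing)
    expect_lte(length(hits), 1L)
    if (length(hits) == 1) expect_equal(hits, nrow(cr))
  }
})

test_that("the multi-diagnosis fraction matches its configured value", {
  stack <- shipped_stack()
  reg <- simulate_cohort(stack, 4000, seed = 77)
  p <- odsreg:::stack_multidx(stack, "60-64")
  obs <- reg$summary$multidx_fraction
  se <- sqrt(p * (1 - p) / 4000)
  expect_lt(abs(obs - p), 3 * se)
})

test_that("per-stratum distribution recovery holds on a mid-sized cohort", {
  stack <- shipped_stack()
  reg <- simulate_cohort(stack, 5000, stratum_weights = c("50-54" = 1),
                         seed = 15)
  tab <- odsreg:::stack_diagnosis_table(stack, "50-54")
  first_dx <- reg$diagnoses[!duplicated(reg$diagnoses$patient_id), ]
  n <- nrow(first_dx)
  freq <- table(first_dx$pathological_structure) / n
  for (i in seq_len(nrow(tab))) {
    w <- tab$weight[i]
    f <- if (tab$category[i] %in% names(freq)) freq[[tab$category[i]]] else 0
    se <- sqrt(w * (1 - w) / n)
    expect_lt(abs(f - w), 3 * se)
  }
})
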