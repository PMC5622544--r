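# Hypergeometric term enrichment of ICD-10 diagnosis annotations across
# patient groups: the upper-tail probability of observing k or more
# annotated diagnoses in a group of n draws from the registry population.

#' Upper-tail hypergeometric enrichment probability
#'
#' Computes `P(X >= k)` for `X` hypergeometric with `population` items of
#' which `M` carry the annotation, in a draw of `n` — the enrichment
#' p-value of a code observed `k` times in a group of `n` diagnoses. The
#' sum is evaluated in log space (log-binomials via `lchoose`) so registry
#' scale counts do not overflow.
#'
#' `k = 0` returns exactly 1 (the empty lower sum); `k > min(M, n)` returns
#' exactly 0 (the event is impossible to exceed).
#'
#' The `as_printed` mode evaluates the literal published formula instead,
#' whose denominator `choose(N, i)` uses the number of distinct codes `N`;
#' it is provided for comparison only and is not a calibrated tail
#' probability (see the methods vignette).
#'
#' @param k annotated diagnoses observed in the group
#' @param M annotated diagnoses in the whole registry
#' @param n diagnoses in the group
#' @param population total diagnoses in the registry
#' @param as_printed evaluate the literal printed formula (default FALSE)
#' @param n_codes the code-universe size `N` used by the printed formula
#' @return probability in `[0, 1]` (the printed-formula mode may leave
#'   `[0, 1]`; values are not clamped there)
#' @examples
#' hypergeom_tail(k = 2, M = 4, n = 5, population = 10)
#' @export
hypergeom_tail <- function(k, M, n, population, as_printed = FALSE,
                           n_codes = NULL) {
  vals <- c(k = k, M = M, n = n, population = population)
  if (any(vals < 0) || any(vals != floor(vals)))
    stop_odsreg("validation", "counts must be non-negative integers")
  if (M > population || n > population)
    stop_odsreg("validation", "M and n cannot exceed the population")
  if (as_printed) {
    if (is.null(n_codes))
      stop_odsreg("validation", "as_printed mode needs n_codes (the N of the formula)")
    if (k == 0) return(1)
    i <- 0:(k - 1)
    return(1 - sum(choose(M, i) * choose(n_codes - M, n - i) / choose(n_codes, i)))
  }
  if (k == 0) return(1)
  if (k > min(M, n)) return(0)
  i <- k:min(M, n)
  logs <- lchoose(M, i) + lchoose(population - M, n - i) - lchoose(population, n)
  m <- max(logs)
  p <- exp(m) * sum(exp(logs - m))
  min(p, 1)
}

#' Enrichment of ICD-10 codes across patient groups
#'
#' Splits the cohort's diagnoses by a grouping datatype property of the
#' patient (e.g. `gender` into M/F) and computes, for every ICD-10 code and
#' group, the upper-tail hypergeometric probability of the code's count in
#' that group given its registry-wide frequency. Counts come from SPARQL
#' queries over the store; the population is all diagnoses in the registry.
#'
#' @param store a `semantic_store`
#' @param cohort a `query_model` with root `Patient` selecting the cohort
#'   (e.g. "patients with a lung-cancer diagnosis")
#' @param group_by grouping datatype property local name (default
#'   `"gender"`)
#' @param groups values of the grouping property to compare (default
#'   `c("M", "F")`)
#' @param codes optional ICD-10 code universe; default: all codes observed
#'   in the cohort's diagnoses
#' @param bh add a Benjamini-Hochberg adjusted column (off by default; the
#'   plain p-values are reported unadjusted)
#' @return data.frame(code, group, population, M, n, k, p_value[, p_bh]);
#'   group sizes are in `attr(, "group_sizes")`
#' @export
enrich_groups <- function(store, cohort, group_by = "gender",
                          groups = c("M", "F"), codes = NULL, bh = FALSE) {
  stopifnot(inherits(store, "semantic_store"))
  ns <- store$namespace
  cohort_pat <- unique(run_query(cohort, store)$s)

  q <- sprintf(paste0(
    "PREFIX ods: <%s>\n",
    "SELECT ?s, ?c, ?p, ?g WHERE {{?s rdf:type ?t FILTER (?t IN (ods:Diagnosis))}.",
    "{{?s ods:icd10_code ?c}.{?s ods:hasPatient ?p}.{?p ods:%s ?g}}}"),
    ns, group_by)
  dx <- execute_sparql(store, q)

  population <- length(unique(dx$s))
  M_by_code <- table(dx$c[!duplicated(dx$s)])
  in_cohort <- dx$p %in% cohort_pat
  if (is.null(codes))
    codes <- sort_c(unique(dx$c[in_cohort]))

  rows <- list()
  sizes <- stats::setNames(integer(length(groups)), groups)
  for (g in groups) {
    sub <- dx[in_cohort & dx$g == g, , drop = FALSE]
    n <- length(unique(sub$s))
    sizes[[g]] <- n
    for (code in codes) {
      k <- length(unique(sub$s[sub$c == code]))
      M <- as.integer(M_by_code[code] %||% 0L)
      if (is.na(M)) M <- 0L
      p <- if (n == 0) 1 else hypergeom_tail(k, M, n, population)
      rows[[length(rows) + 1L]] <- data.frame(
        code = code, group = g, population = population, M = M, n = n, k = k,
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (bh) out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "group_sizes") <- sizes
  out
}
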