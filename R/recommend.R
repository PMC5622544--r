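# Treatment recommendation: an empirical tree of therapy-class sequences by
# period, built from the profiles of the patients matching a feature
# filter. Cycles (repeated application of the same therapy) are handled by
# unrolling over periods up to a bound, so the tree is acyclic by
# construction; probabilities are empirical conditional frequencies.

NO_FURTHER <- "no_further_therapy"

# Therapy-class sequence per patient, ordered by start date, collapsed to
# one class per period (month or quarter from the first therapy).
therapy_sequences <- function(store, patients, period = c("month", "quarter")) {
  period <- match.arg(period)
  ix <- store_index(store)
  ns <- store$namespace
  lapply(stats::setNames(patients, patients), function(p) {
    ths <- sort_c(lookup_objs(ix, "hasTherapy", p))
    ths <- ths[grepl("/therapies/", ths)]
    if (length(ths) == 0) return(character(0))
    starts <- vapply(ths, function(t) lookup_val(ix, "start_date", t),
                     character(1))
    ord <- order(starts, ths, method = "radix")
    ths <- ths[ord]; starts <- starts[ord]
    pm <- months_between(starts, starts[1])
    pid <- if (period == "month") pm else pm %/% 3L
    keep <- !duplicated(pid)
    iri_local(unname(ix$type_of[ths[keep]]), ns)
  })
}

build_node <- function(seqs, depth, max_period) {
  support <- length(seqs)
  ended <- vapply(seqs, function(s) length(s) < depth, logical(1))
  nxt <- vapply(seqs[!ended], function(s) s[[depth]], character(1))
  kids <- list()
  if (depth <= max_period) {
    for (cl in sort_c(unique(nxt))) {
      sub <- seqs[!ended][nxt == cl]
      kids[[cl]] <- build_node(sub, depth + 1L, max_period)
      kids[[cl]]$label <- cl
      kids[[cl]]$prob <- length(sub) / support
    }
  }
  n_end <- sum(ended) + if (depth > max_period) length(nxt) else 0L
  if (n_end > 0) {
    kids[[NO_FURTHER]] <- list(label = NO_FURTHER, prob = n_end / support,
                               support = n_end, children = list())
  }
  list(label = NULL, prob = 1, support = support, children = kids)
}

#' Build a treatment-sequence tree for a patient cohort
#'
#' Retrieves the patients matching the feature filter, extracts their
#' therapy-class sequences by period, and builds the tree in which the node
#' at path (t1, ..., tp) carries the empirical conditional probability that
#' a cohort patient's p-th therapy is tp given the prefix, alongside its
#' support count. Every node has an explicit "no further therapy" child for
#' the patients whose sequence ends there, so children probabilities sum to
#' one and child supports sum to the parent support.
#'
#' @param store a `semantic_store`
#' @param cohort a `query_model` selecting the cohort (root `Patient`)
#' @param period `"month"` (default) or `"quarter"`: how therapy start
#'   dates are binned into sequence positions
#' @param max_period unroll bound (default 24 periods)
#' @param laplace add-one smoothing of child probabilities (off by default)
#' @return an object of class `treatment_tree`
#' @export
build_treatment_tree <- function(store, cohort, period = "month",
                                 max_period = 24L, laplace = FALSE) {
  pats <- sort_c(unique(run_query(cohort, store)$s))
  if (length(pats) == 0)
    stop_odsreg("validation", "cohort is empty")
  seqs <- therapy_sequences(store, pats, period)
  root <- build_node(seqs, 1L, as.integer(max_period))
  root$label <- "cohort"
  if (laplace) root <- laplace_node(root)
  structure(list(root = root, period = period,
                 max_period = as.integer(max_period),
                 n_patients = length(pats)),
            class = "treatment_tree")
}

laplace_node <- function(node) {
  kids <- node$children
  if (length(kids) > 0) {
    tot <- node$support + length(kids)
    for (nm in names(kids)) {
      kids[[nm]]$prob <- (kids[[nm]]$support + 1) / tot
      kids[[nm]] <- laplace_node(kids[[nm]])
    }
    node$children <- kids
  }
  node
}

#' @export
print.treatment_tree <- function(x, ...) {
  cat("<treatment_tree> ", x$n_patients, " patients, period = ", x$period,
      ", max ", x$max_period, " periods\n", sep = "")
  invisible(x)
}

walk_path <- function(tree, path) {
  node <- tree$root
  used <- character(0)
  for (cl in path) {
    if (!cl %in% names(node$children)) return(list(node = node, used = used,
                                                   exact = FALSE))
    node <- node$children[[cl]]
    used <- c(used, cl)
  }
  list(node = node, used = used, exact = TRUE)
}

#' Rank the likely next therapies after an observed treatment path
#'
#' Walks the tree along the observed therapy-class path and ranks the
#' children of the reached node by conditional probability (ties broken
#' lexicographically). When the full path is not present in the tree the
#' longest matching prefix is used and the result is flagged.
#'
#' @param tree a `treatment_tree`
#' @param path character vector of observed therapy classes (possibly
#'   empty: ranks first-period therapies)
#' @return data.frame(therapy, probability, support) ordered by decreasing
#'   probability; attributes `exact_path` (logical) and `used_path`
#' @export
recommend_next <- function(tree, path = character(0)) {
  stopifnot(inherits(tree, "treatment_tree"))
  w <- walk_path(tree, path)
  kids <- w$node$children
  if (length(kids) == 0) {
    out <- data.frame(therapy = NO_FURTHER, probability = 1,
                      support = w$node$support, stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      therapy = vapply(kids, `[[`, character(1), "label"),
      probability = vapply(kids, `[[`, numeric(1), "prob"),
      support = vapply(kids, `[[`, numeric(1), "support"),
      stringsAsFactors = FALSE)
    out <- out[order(-out$probability, out$therapy, method = "radix"), ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "exact_path") <- w$exact
  attr(out, "used_path") <- w$used
  out
}

#' Export a treatment tree as JSON
#' @param tree a `treatment_tree`
#' @param path output file
#' @return invisibly, the path
#' @export
tree_to_json <- function(tree, path) {
  jsonlite::write_json(unclass(tree), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
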