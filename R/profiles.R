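# Semantic profiles: the subset of an individual's datatype values and
# linked individuals selected for an analysis — a recursive union of
# selected datatype assertions and the profiles of linked objects, with a
# path-based cycle guard and a depth bound.

#' Property selection for a semantic profile
#'
#' @param datatype_props character vector of datatype property local names
#' @param object_props named list: object property local name ->
#'   nested `property_selection` for the linked individuals
#' @param max_depth recursion bound (>= 1)
#' @return an object of class `property_selection`
#' @export
property_selection <- function(datatype_props = character(0),
                               object_props = list(), max_depth = 4L) {
  if (max_depth < 1) stop_odsreg("validation", "max_depth must be >= 1")
  structure(list(datatype_props = datatype_props,
                 object_props = object_props,
                 max_depth = as.integer(max_depth)),
            class = "property_selection")
}

#' Extract the semantic profile of an individual
#'
#' Collects the selected datatype assertions of `subject` and recursively
#' the profiles of individuals linked through the selected object
#' properties. Recursion stops at `max_depth` and never revisits an IRI
#' already on the current path, so extraction terminates on any finite
#' graph, cyclic or not.
#'
#' @param store a `semantic_store`
#' @param subject individual IRI
#' @param sel a `property_selection`
#' @return an object of class `semantic_profile`: `subject`, `type`,
#'   `values` (named list of literal vectors), `links` (named list of
#'   profile lists)
#' @export
extract_profile <- function(store, subject, sel) {
  stopifnot(inherits(store, "semantic_store"),
            inherits(sel, "property_selection"))
  tr <- store$triples
  if (!subject %in% tr$s)
    stop_odsreg("lookup", "unknown subject IRI: %s", subject)
  ns <- store$namespace
  extract <- function(subj, sel, depth, path) {
    rows <- tr[tr$s == subj, , drop = FALSE]
    type <- rows$o[rows$p == RDF_TYPE][1]
    values <- list()
    for (pr in sel$datatype_props) {
      v <- rows$o[rows$p == iri_expand(pr, ns) & rows$o_kind == "literal"]
      if (length(v) > 0) values[[pr]] <- v
    }
    links <- list()
    if (depth < sel$max_depth) {
      for (pr in names(sel$object_props)) {
        objs <- rows$o[rows$p == iri_expand(pr, ns) & rows$o_kind == "iri"]
        objs <- setdiff(sort_c(objs), path)  # cycle guard: skip IRIs on path
        if (length(objs) > 0) {
          nested <- sel$object_props[[pr]]
          links[[pr]] <- lapply(objs, function(o)
            extract(o, nested, depth + 1L, c(path, o)))
        }
      }
    }
    structure(list(subject = subj,
                   type = if (is.na(type)) NULL else iri_local(type, ns),
                   values = values, links = links),
              class = "semantic_profile")
  }
  extract(subject, sel, 0L, subject)
}

#' @export
print.semantic_profile <- function(x, ...) {
  cat("<semantic_profile> ", x$subject,
      if (!is.null(x$type)) paste0(" (", x$type, ")"),
      ": ", length(x$values), " values, ",
      sum(lengths(x$links)), " linked profiles\n", sep = "")
  invisible(x)
}

# Flatten a profile into a data.frame(path, property, value) for export.
#' Flatten a semantic profile
#' @param profile a `semantic_profile`
#' @return data.frame with columns `subject`, `property`, `value`
#' @export
flatten_profile <- function(profile) {
  rows <- list()
  walk <- function(p) {
    for (pr in names(p$values))
      for (v in p$values[[pr]])
        rows[[length(rows) + 1L]] <<- data.frame(
          subject = p$subject, property = pr, value = v,
          stringsAsFactors = FALSE)
    for (pr in names(p$links))
      for (child in p$links[[pr]]) walk(child)
  }
  walk(profile)
  if (length(rows) == 0)
    return(data.frame(subject = character(0), property = character(0),
                      value = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
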