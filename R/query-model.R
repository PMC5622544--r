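# Ontology-driven search (ODS): incremental query models built from ontology
# classes and properties, compiled to SPARQL without the user writing query
# text. Emission is deterministic: the same model always yields the same
# byte sequence, with the variable naming convention of the query templates
# (?s for the root, ?a0/?a1/... for root children, parent name + per-depth
# counter for deeper nodes, ?t/?ta0/... for type variables).

#' Object-property hop of a query model
#'
#' @param property object property local name (e.g. `"hasDiagnosis"`)
#' @param class target class local name; expanded to its subclass closure at
#'   emission
#' @param children list of nested [hop()] / [filt()] nodes
#' @return a node for [query_model()]
#' @export
hop <- function(property, class, children = list()) {
  structure(list(kind = "hop", property = property, class = class,
                 children = children), class = "ods_node")
}

#' Datatype filter of a query model
#'
#' @param property datatype property local name (e.g. `"age"`)
#' @param op one of `=`, `!=`, `<`, `<=`, `>`, `>=`; string-valued
#'   properties use `=`/`!=` and are emitted through `str()` coercion
#' @param value literal (number or string); the string `"?"` or `"?name"`
#'   marks a parameter slot to be filled by [instantiate_template()]
#' @return a node for [query_model()]
#' @export
filt <- function(property, op, value) {
  if (!op %in% c("=", "!=", "<", "<=", ">", ">="))
    stop_odsreg("validation", "unsupported filter operator '%s'", op)
  structure(list(kind = "filt", property = property, op = op, value = value,
                 children = list()), class = "ods_node")
}

#' Aggregation clause of a query model
#'
#' @param fun one of `"count"`, `"avg"`, `"min"`, `"max"`
#' @param distinct logical; `count(DISTINCT ?s)` when TRUE
#' @param group_by `"type"` to group by the root's type variable (the shape
#'   of the dashboard queries), or a datatype property local name
#' @param var aggregated variable: `"root"` (default) aggregates the root
#'   subject; a datatype property name aggregates that property's values
#' @return aggregation spec for [query_model()]
#' @export
aggregate_by <- function(fun = "count", distinct = TRUE, group_by = "type",
                         var = "root") {
  if (!fun %in% AGG_FUNS)
    stop_odsreg("validation", "unsupported aggregate '%s'", fun)
  list(fun = fun, distinct = distinct, group_by = group_by, var = var)
}

#' Build an incremental query model
#'
#' The entry point of the ontology-driven search: choose a root class, then
#' refine with object-property hops (with type constraints) and datatype
#' filters; optionally aggregate. Compiled to SPARQL by [build_query()].
#'
#' @param root_class root class local name (e.g. `"Patient"`)
#' @param children list of [hop()] / [filt()] nodes
#' @param aggregation optional [aggregate_by()] clause
#' @param name optional template name
#' @param namespace project namespace
#' @return an object of class `query_model`
#' @examples
#' qm <- query_model("Patient", children = list(
#'   hop("hasDiagnosis", "Diagnosis", children = list(
#'     hop("hasPathologicalStructure", "Colorectal_cancer"))),
#'   filt("gender", "=", "M"),
#'   filt("age", ">=", 50),
#'   filt("age", "<=", 70),
#'   hop("hasTherapy", "Chemotherapy")))
#' @export
query_model <- function(root_class, children = list(), aggregation = NULL,
                        name = NULL, namespace = DEFAULT_NS) {
  structure(list(root_class = root_class, children = children,
                 aggregation = aggregation, name = name,
                 namespace = namespace),
            class = "query_model")
}

#' @export
print.query_model <- function(x, ...) {
  cat("<query_model> root:", x$root_class,
      if (!is.null(x$aggregation)) paste0("(", x$aggregation$fun, " by ",
                                          x$aggregation$group_by, ")"),
      "\n")
  invisible(x)
}

# Validate a model against the ontology; returns property metadata lookups.
validate_model <- function(model, ontology) {
  ns <- model$namespace
  cls <- ontology$classes
  dtp <- ontology$datatype_properties
  obp <- ontology$object_properties
  root_iri <- iri_expand(model$root_class, ns)
  if (!root_iri %in% cls)
    stop_odsreg("validation", "unknown root class %s", model$root_class)
  ancestors_ok <- function(node_class, domain) {
    iri_expand(node_class, ns) %in% subclass_closure(ontology, domain)
  }
  check_node <- function(node, node_class) {
    if (node$kind == "hop") {
      prop <- iri_expand(node$property, ns)
      rows <- obp[obp$iri == prop, , drop = FALSE]
      if (nrow(rows) == 0)
        stop_odsreg("validation", "unknown object property %s", node$property)
      ok <- any(vapply(rows$domain, function(d) ancestors_ok(node_class, d),
                       logical(1)))
      if (!ok)
        stop_odsreg("validation", "property %s does not apply to class %s",
                    node$property, node_class)
      if (!iri_expand(node$class, ns) %in% cls)
        stop_odsreg("validation", "unknown class %s", node$class)
      for (ch in node$children) check_node(ch, node$class)
    } else {
      prop <- iri_expand(node$property, ns)
      rows <- dtp[dtp$iri == prop, , drop = FALSE]
      if (nrow(rows) == 0)
        stop_odsreg("validation", "unknown datatype property %s", node$property)
      ok <- any(vapply(rows$domain, function(d) ancestors_ok(node_class, d),
                       logical(1)))
      if (!ok)
        stop_odsreg("validation", "property %s does not apply to class %s",
                    node$property, node_class)
      kind <- rows$kind[1]
      if (is.character(node$value) && startsWith(node$value, "?"))
        stop_odsreg("validation",
                    "parameter slot '%s' not instantiated (property %s)",
                    node$value, node$property)
      if (kind %in% c("integer", "decimal")) {
        if (is.na(suppressWarnings(as.numeric(node$value))))
          stop_odsreg("validation", "filter on numeric property %s needs a number",
                      node$property)
      } else if (!node$op %in% c("=", "!="))
        stop_odsreg("validation", "operator %s not valid for %s property %s",
                    node$op, kind, node$property)
    }
  }
  for (ch in model$children) check_node(ch, model$root_class)
  if (!is.null(model$aggregation)) {
    gb <- model$aggregation$group_by
    if (!identical(gb, "type")) {
      prop <- iri_expand(gb, ns)
      if (!prop %in% dtp$iri)
        stop_odsreg("validation", "group_by property %s unknown", gb)
    }
  }
  invisible(TRUE)
}

# Datatype kind of a property (first declaration wins).
dtp_kind <- function(ontology, ns, property) {
  rows <- ontology$datatype_properties
  k <- rows$kind[rows$iri == iri_expand(property, ns)]
  if (length(k) == 0) NA_character_ else k[1]
}

#' Compile a query model to SPARQL
#'
#' Emits the template shape of the ontology-driven search: every node
#' contributes a type block `?x rdf:type ?tx FILTER (?tx IN (<subclass
#' closure>))`, object hops contribute `?parent <prop> ?x`, datatype filters
#' contribute `FILTER` clauses (numeric comparison, or `str()` equality for
#' strings), and aggregation emits `SELECT count(DISTINCT ?s), ?t ... group
#' by ?t`. Emission is deterministic.
#'
#' @param model a `query_model`
#' @param ontology an `ontology_model`
#' @return SPARQL SELECT string
#' @export
build_query <- function(model, ontology) {
  stopifnot(inherits(model, "query_model"))
  validate_model(model, ontology)
  ns <- model$namespace
  pname <- function(local) paste0("ods:", local)
  closure_list <- function(class_local) {
    cl <- subclass_closure(ontology, iri_expand(class_local, ns))
    paste(vapply(iri_local(cl, ns), pname, character(1)), collapse = ", ")
  }
  depth_counter <- new.env(parent = emptyenv())
  next_depth_var <- function(parent_var, depth) {
    key <- as.character(depth)
    k <- (depth_counter[[key]] %||% 0L) + 1L
    depth_counter[[key]] <- k
    paste0(parent_var, k)
  }
  items <- character(0)
  emit_node <- function(node, parent_var, var) {
    if (node$kind == "hop") {
      tvar <- paste0("t", var)
      items <<- c(items, sprintf("{?%s ods:%s ?%s.{?%s rdf:type ?%s FILTER (?%s IN (%s))}}",
                                 parent_var, node$property, var, var, tvar,
                                 tvar, closure_list(node$class)))
      depth <- nchar(var) - 1L + 1L  # children of ?aX live at depth+1
      for (ch in node$children)
        emit_node(ch, var, next_depth_var(var, depth))
    } else {
      kind <- dtp_kind(ontology, ns, node$property)
      expr <- if (kind %in% c("integer", "decimal")) {
        sprintf("?%s %s %s", var, node$op, as.character(node$value))
      } else {
        sprintf("str(?%s) %s '%s'", var, node$op, node$value)
      }
      items <<- c(items, sprintf("{?%s ods:%s ?%s. FILTER (%s)}",
                                 parent_var, node$property, var, expr))
    }
  }
  children <- model$children
  agg <- model$aggregation
  group_var <- NULL
  if (!is.null(agg) && !identical(agg$group_by, "type")) {
    children <- c(children, list(structure(
      list(kind = "gprop", property = agg$group_by), class = "ods_node")))
  }
  root_children_vars <- paste0("a", seq_along(children) - 1L)
  for (k in seq_along(children)) {
    node <- children[[k]]
    var <- root_children_vars[k]
    if (identical(node$kind, "gprop")) {
      items <- c(items, sprintf("{?s ods:%s ?%s}", node$property, var))
      group_var <- var
    } else {
      emit_node(node, "s", var)
    }
  }
  root_block <- sprintf("{?s rdf:type ?t FILTER (?t IN (%s))}",
                        closure_list(model$root_class))
  body <- if (length(items) == 0) sprintf("{%s}", root_block) else
    sprintf("{%s.{%s}}", root_block, paste(items, collapse = ".\n"))

  if (is.null(agg)) {
    select <- "SELECT DISTINCT ?s"
    suffix <- ""
  } else {
    target <- if (identical(agg$var, "root")) "?s" else paste0("?", agg$var)
    fun_txt <- sprintf("%s(%s%s)", agg$fun,
                       if (agg$distinct) "DISTINCT " else "", target)
    if (identical(agg$group_by, "type")) {
      select <- sprintf("SELECT %s, ?t", fun_txt)
      suffix <- " group by ?t"
    } else {
      select <- sprintf("SELECT %s, ?%s", fun_txt, group_var)
      suffix <- sprintf(" group by ?%s", group_var)
    }
  }
  sprintf("PREFIX ods: <%s>\n%s WHERE %s%s", ns, select, body, suffix)
}

#' Run a query model against a store
#'
#' Equivalent to `execute_sparql(store, build_query(model, store$ontology))`.
#'
#' @param model a `query_model`
#' @param store a `semantic_store`
#' @return result data.frame (see [execute_sparql()])
#' @export
run_query <- function(model, store) {
  execute_sparql(store, build_query(model, store$ontology))
}

# ---- template persistence ------------------------------------------------

node_to_list <- function(node) {
  if (node$kind == "hop")
    list(kind = "hop", property = node$property, class = node$class,
         children = lapply(node$children, node_to_list))
  else
    list(kind = "filt", property = node$property, op = node$op,
         value = node$value)
}

node_from_list <- function(x) {
  if (x$kind == "hop")
    hop(x$property, x$class, children = lapply(x$children, node_from_list))
  else
    filt(x$property, x$op, x$value)
}

#' Save a query model as a JSON template
#'
#' Templates are versioned JSON and may contain parameter slots (filter
#' values `"?"` or `"?name"`) filled at load time.
#'
#' @param model a `query_model`
#' @param path output JSON path
#' @return invisibly, the path
#' @export
save_template <- function(model, path) {
  obj <- list(schema_version = 1L,
              root_class = model$root_class,
              children = lapply(model$children, node_to_list),
              aggregation = model$aggregation,
              name = model$name,
              namespace = model$namespace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Load a query model from a JSON template
#'
#' @param path JSON file written by [save_template()]
#' @param params optional named list filling parameter slots (see
#'   [instantiate_template()])
#' @return a `query_model`
#' @export
load_template <- function(path, params = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L)
    stop_odsreg("format", "unsupported template schema version")
  agg <- obj$aggregation
  if (!is.null(agg))
    agg <- aggregate_by(agg$fun, isTRUE(agg$distinct), agg$group_by,
                        agg$var %||% "root")
  model <- query_model(obj$root_class,
                       children = lapply(obj$children, node_from_list),
                       aggregation = agg, name = obj$name,
                       namespace = obj$namespace %||% DEFAULT_NS)
  if (!is.null(params)) model <- instantiate_template(model, params)
  model
}

#' Fill the parameter slots of a template
#'
#' A filter value `"?"` is matched by its property name; `"?slot"` by the
#' explicit slot name.
#'
#' @param model a `query_model` with parameter slots
#' @param params named list, e.g. `list(age = 60)`
#' @return the instantiated `query_model`
#' @export
instantiate_template <- function(model, params) {
  fill <- function(node) {
    if (node$kind == "hop") {
      node$children <- lapply(node$children, fill)
      return(node)
    }
    v <- node$value
    if (is.character(v) && startsWith(v, "?")) {
      slot <- if (v == "?") node$property else substring(v, 2L)
      if (!slot %in% names(params))
        stop_odsreg("validation", "no value supplied for parameter '%s'", slot)
      node$value <- params[[slot]]
    }
    node
  }
  model$children <- lapply(model$children, fill)
  model
}

# ---- defined classes -----------------------------------------------------

#' Create a defined class
#'
#' A defined class is a named class whose membership is computed by running
#' a stored (non-aggregating) query; it is virtual — membership is
#' recomputed on demand, no triples are materialised.
#'
#' @param name class label, e.g. `"Patient with colorectal cancer"`
#' @param query a `query_model` without aggregation
#' @return an object of class `defined_class`
#' @export
defined_class <- function(name, query) {
  if (!is.null(query$aggregation))
    stop_odsreg("validation", "a defined class query must not aggregate")
  structure(list(name = name, query = query), class = "defined_class")
}

#' Register a defined class on a store and return its members
#'
#' @param dc a `defined_class`
#' @param store a `semantic_store`
#' @return character vector of member IRIs (current membership)
#' @export
register_defined_class <- function(dc, store) {
  stopifnot(inherits(dc, "defined_class"))
  local <- iri_local(store$ontology$classes, store$namespace)
  if (dc$name %in% local)
    stop_odsreg("validation", "defined class name '%s' collides with an ontology class",
                dc$name)
  store$defined_classes[[dc$name]] <- dc$query
  defined_class_members(dc$name, store)
}

#' Current membership of a registered defined class
#' @param name defined class name
#' @param store a `semantic_store`
#' @return character vector of member IRIs
#' @export
defined_class_members <- function(name, store) {
  q <- store$defined_classes[[name]]
  if (is.null(q)) stop_odsreg("lookup", "no defined class '%s'", name)
  res <- run_query(q, store)
  sort_c(unique(res$s))
}

# ---- dashboards ----------------------------------------------------------

#' Evaluate dashboard queries into key-value tables
#'
#' Each model must carry an aggregation; its result is reduced to ordered
#' (key, value) pairs where keys are group labels (class or literal local
#' names) and values are numeric — the tabular half of a semantic dashboard.
#'
#' @param models named list of aggregation `query_model`s (names become
#'   labels)
#' @param store a `semantic_store`
#' @return list of `list(label =, table = data.frame(key, value))`
#' @export
dashboard_result <- function(models, store) {
  if (inherits(models, "query_model")) models <- list(models)
  labels <- names(models) %||% vapply(seq_along(models), function(i)
    models[[i]]$name %||% paste0("dashboard_", i), character(1))
  out <- vector("list", length(models))
  for (i in seq_along(models)) {
    m <- models[[i]]
    if (is.null(m$aggregation))
      stop_odsreg("validation", "dashboard model '%s' has no aggregation",
                  labels[[i]])
    res <- run_query(m, store)
    agg_col <- grep("^(count|avg|min|max)_", names(res), value = TRUE)[1]
    key_col <- setdiff(names(res), agg_col)
    if (length(key_col) == 0) {
      tab <- data.frame(key = labels[[i]], value = as.numeric(res[[agg_col]]),
                        stringsAsFactors = FALSE)
    } else {
      keys <- iri_local(as.character(res[[key_col[1]]]), store$namespace)
      tab <- data.frame(key = keys, value = as.numeric(res[[agg_col]]),
                        stringsAsFactors = FALSE)
      tab <- tab[order(tab$key, method = "radix"), , drop = FALSE]
      rownames(tab) <- NULL
    }
    out[[i]] <- list(label = labels[[i]], table = tab)
  }
  out
}
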