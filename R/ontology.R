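# Ontology model: classes, property declarations and the subclass hierarchy
# that drive transformation, query emission and subclass-closure expansion.

#' Load a cancer-registry ontology from Turtle
#'
#' Reads an OWL ontology restricted to class declarations, `rdfs:subClassOf`,
#' property domain/range declarations and annotations, and returns the
#' in-memory model used by the rest of the package.
#'
#' The model must declare the five core registry classes (`Patient`,
#' `Patient_condition`, `Diagnosis`, `Therapy`, `Disease_course`); a file
#' without them is rejected as schema-invalid. The subclass graph must be
#' acyclic and every property domain/range IRI must be a declared class.
#'
#' @param path path to a Turtle file; defaults to the ontology shipped with
#'   the package
#' @param namespace project namespace IRI prefix; class and property IRIs are
#'   reported relative to it
#' @return an object of class `ontology_model` with elements `classes`,
#'   `datatype_properties` (data.frame iri/domain/kind),
#'   `object_properties` (data.frame iri/domain/range), `subclass_edges`
#'   (data.frame parent/child), `namespace`, `prefixes`
#' @examples
#' onto <- load_ontology()
#' subclass_closure(onto, ods_iri("Brachytherapy"))
#' @export
load_ontology <- function(path = ods_example("cancer-registry.ttl"),
                          namespace = DEFAULT_NS) {
  parsed <- read_turtle(path)
  tr <- parsed$triples
  classes <- sort_c(unique(tr$s[tr$p == RDF_TYPE & tr$o == OWL_CLASS &
                                  tr$o_kind == "iri"]))
  core <- paste0(namespace, c("Patient", "Patient_condition", "Diagnosis",
                              "Therapy", "Disease_course"))
  missing <- core[!core %in% classes]
  if (length(missing) > 0)
    stop_odsreg("schema", "ontology is missing core class(es): %s",
                paste(iri_local(missing, namespace), collapse = ", "))

  sub <- tr[tr$p == RDFS_SUBCLASSOF & tr$o_kind == "iri", c("s", "o")]
  subclass_edges <- data.frame(parent = sub$o, child = sub$s,
                               stringsAsFactors = FALSE)
  undeclared <- setdiff(unique(c(subclass_edges$parent, subclass_edges$child)),
                        classes)
  if (length(undeclared) > 0)
    stop_odsreg("schema", "subClassOf involves undeclared class(es): %s",
                paste(iri_local(undeclared, namespace), collapse = ", "))

  prop_rows <- function(prop_type) {
    props <- unique(tr$s[tr$p == RDF_TYPE & tr$o == prop_type])
    if (length(props) == 0)
      return(data.frame(iri = character(0), domain = character(0),
                        range = character(0), stringsAsFactors = FALSE))
    do.call(rbind, lapply(sort_c(props), function(pr) {
      doms <- sort_c(unique(tr$o[tr$s == pr & tr$p == RDFS_DOMAIN]))
      rans <- sort_c(unique(tr$o[tr$s == pr & tr$p == RDFS_RANGE]))
      if (length(doms) == 0 || length(rans) == 0)
        stop_odsreg("schema", "property %s lacks domain or range",
                    iri_local(pr, namespace))
      expand.grid(iri = pr, domain = doms, range = rans,
                  stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    }))
  }
  dtp <- prop_rows(OWL_DATATYPE_PROPERTY)
  kind <- names(XSD_KINDS)[match(dtp$range, XSD_KINDS)]
  if (anyNA(kind) && nrow(dtp) > 0)
    stop_odsreg("schema", "datatype property with unsupported range: %s",
                paste(unique(dtp$iri[is.na(kind)]), collapse = ", "))
  datatype_properties <- data.frame(iri = dtp$iri, domain = dtp$domain,
                                    kind = kind, stringsAsFactors = FALSE)
  object_properties <- prop_rows(OWL_OBJECT_PROPERTY)

  bad_dom <- setdiff(unique(c(datatype_properties$domain,
                              object_properties$domain,
                              object_properties$range)), classes)
  if (length(bad_dom) > 0)
    stop_odsreg("schema", "property domain/range not a declared class: %s",
                paste(iri_local(bad_dom, namespace), collapse = ", "))

  model <- structure(list(classes = classes,
                          datatype_properties = datatype_properties,
                          object_properties = object_properties,
                          subclass_edges = subclass_edges,
                          namespace = namespace,
                          prefixes = parsed$prefixes),
                     class = "ontology_model")
  check_acyclic(model)
  model
}

# Topological check of the subclass graph; errors on a cycle.
check_acyclic <- function(model) {
  edges <- model$subclass_edges
  if (nrow(edges) == 0) return(invisible(TRUE))
  indeg <- table(factor(edges$child, levels = model$classes))
  queue <- names(indeg)[indeg == 0]
  removed <- 0L
  indeg <- as.integer(indeg)
  names(indeg) <- model$classes
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    removed <- removed + 1L
    kids <- edges$child[edges$parent == v]
    for (k in kids) {
      indeg[[k]] <- indeg[[k]] - 1L
      if (indeg[[k]] == 0L) queue <- c(queue, k)
    }
  }
  if (removed < length(model$classes))
    stop_odsreg("schema", "subclass graph contains a cycle")
  invisible(TRUE)
}

#' Subclass closure of an ontology class
#'
#' Returns the transitive descendants of `root` in depth-first pre-order with
#' lexicographic (byte order) sibling ordering, with `root` itself appended
#' last — the enumeration order used when a type constraint is inlined into a
#' SPARQL `FILTER (?t IN (...))` clause.
#'
#' @param model an `ontology_model`
#' @param root class IRI
#' @return character vector of class IRIs; `root` is always the last element
#' @export
subclass_closure <- function(model, root) {
  stopifnot(inherits(model, "ontology_model"))
  if (!root %in% model$classes)
    stop_odsreg("lookup", "unknown class IRI: %s", root)
  edges <- model$subclass_edges
  children_of <- function(p) sort_c(edges$child[edges$parent == p])
  out <- character(0)
  walk <- function(node) {
    for (ch in children_of(node)) {
      out <<- c(out, ch)
      walk(ch)
    }
  }
  walk(root)
  c(unique(out), root)
}

#' Shipped example file path
#' @param file file name under the package's `extdata`
#' @return absolute path
#' @export
ods_example <- function(file) {
  p <- system.file("extdata", file, package = "odsreg", mustWork = FALSE)
  if (p == "") stop_odsreg("lookup", "no shipped file '%s'", file)
  p
}

#' Expand a local name in the project namespace
#' @param local class or property local name (e.g. `"Patient"`)
#' @param ns namespace IRI prefix
#' @return full IRI
#' @export
ods_iri <- function(local, ns = DEFAULT_NS) iri_expand(local, ns)

is_subclass_of <- function(model, class_iri, ancestor) {
  class_iri %in% subclass_closure(model, ancestor)
}

#' @export
print.ontology_model <- function(x, ...) {
  cat("<ontology_model> ", length(x$classes), " classes, ",
      length(unique(x$datatype_properties$iri)), " datatype properties, ",
      length(unique(x$object_properties$iri)), " object properties\n",
      "namespace: ", x$namespace, "\n", sep = "")
  invisible(x)
}
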