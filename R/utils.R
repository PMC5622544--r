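# Shared internal helpers: IRI handling, month arithmetic, small utilities.

STD_PREFIXES <- c(
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl  = "http://www.w3.org/2002/07/owl#",
  xsd  = "http://www.w3.org/2001/XMLSchema#"
)

DEFAULT_NS <- "http://www.imib.es/ontologies/disease-times#"

RDF_TYPE <- paste0(STD_PREFIXES[["rdf"]], "type")
RDFS_SUBCLASSOF <- paste0(STD_PREFIXES[["rdfs"]], "subClassOf")
RDFS_DOMAIN <- paste0(STD_PREFIXES[["rdfs"]], "domain")
RDFS_RANGE <- paste0(STD_PREFIXES[["rdfs"]], "range")
OWL_CLASS <- paste0(STD_PREFIXES[["owl"]], "Class")
OWL_DATATYPE_PROPERTY <- paste0(STD_PREFIXES[["owl"]], "DatatypeProperty")
OWL_OBJECT_PROPERTY <- paste0(STD_PREFIXES[["owl"]], "ObjectProperty")

XSD_KINDS <- c(
  string  = "http://www.w3.org/2001/XMLSchema#string",
  integer = "http://www.w3.org/2001/XMLSchema#integer",
  decimal = "http://www.w3.org/2001/XMLSchema#decimal",
  date    = "http://www.w3.org/2001/XMLSchema#date"
)

#' Local name of an IRI relative to a namespace
#' @param iri character vector of IRIs
#' @param ns namespace prefix string
#' @return local names where `iri` starts with `ns`, else the full IRI
#' @keywords internal
iri_local <- function(iri, ns = DEFAULT_NS) {
  ifelse(startsWith(iri, ns), substring(iri, nchar(ns) + 1L), iri)
}

#' Expand a local name to a full IRI under a namespace
#' @keywords internal
iri_expand <- function(local, ns = DEFAULT_NS) {
  ifelse(grepl("^https?://", local), local, paste0(ns, local))
}

# Byte-order (C locale) sort, used wherever deterministic ordering matters.
sort_c <- function(x) sort(x, method = "radix")

# Calendar-month index of an ISO date string or Date (year*12 + month).
month_number <- function(d) {
  d <- as.Date(d)
  lt <- as.POSIXlt(d)
  lt$year * 12L + lt$mon
}

# Months elapsed from `origin` to `d` in whole calendar months (0-based).
months_between <- function(d, origin) month_number(d) - month_number(origin)

# Epoch days of the first of every month 1900-01 .. 2069-12, for integer
# calendar arithmetic (index i = months since 1900-01).
MONTH_STARTS <- as.integer(seq(as.Date("1900-01-01"), as.Date("2070-01-01"),
                               by = "month"))

# Months since 1900-01 of an integer epoch day (vectorised).
monthnum_int <- function(d_int) findInterval(d_int, MONTH_STARTS)

# Add k calendar months to an integer epoch day, clamping the day-of-month.
add_months_int <- function(d_int, k) {
  mn <- findInterval(d_int, MONTH_STARTS)
  day_off <- d_int - MONTH_STARTS[mn]
  tm <- mn + as.integer(k)
  pmin.int(MONTH_STARTS[tm] + day_off, MONTH_STARTS[tm + 1L] - 1L)
}

# Add k calendar months to a Date, clamping the day-of-month.
add_months <- function(d, k) {
  as.Date(add_months_int(as.integer(as.Date(d)), k), origin = "1970-01-01")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_odsreg <- function(kind, fmt, ...) {
  stop(structure(
    class = c(paste0("odsreg_", kind, "_error"), "odsreg_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
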