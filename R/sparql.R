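# SPARQL SELECT subset: parser and evaluator for the conjunctive dialect the
# ontology-driven search emits — nested group graph patterns (joins), type
# constraints with FILTER (?t IN (...)), datatype comparators, str()
# equality, DISTINCT, count/avg/min/max with group by, order by.

sparql_tokenize <- function(query) {
  pat <- paste0(
    "<[^>]*>",                                     # IRI
    "|'(?:[^'\\\\]|\\\\.)*'",                      # single-quoted literal
    "|\"(?:[^\"\\\\]|\\\\.)*\"",                   # double-quoted literal
    "|\\?[A-Za-z0-9_]+",                           # variable
    "|>=|<=|!=",                                   # two-char comparators
    "|[A-Za-z][A-Za-z0-9_-]*:[A-Za-z0-9_.-]*",     # prefixed name (dots kept)
    "|[+-]?[0-9]+(?:\\.[0-9]+)?",                  # number
    "|[{}().,;=<>*]",                              # punctuation
    "|[A-Za-z][A-Za-z0-9_]*"                       # bare keyword/name
  )
  m <- gregexpr(pat, query, perl = TRUE)[[1]]
  if (m[1] == -1) stop_odsreg("query", "empty query")
  toks <- regmatches(query, gregexpr(pat, query, perl = TRUE))[[1]]
  # a prefixed name ending in '.' is a statement dot unless another name
  # character or list delimiter follows it in the source
  ends <- m + attr(m, "match.length") - 1L
  out <- list()
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (grepl("^[A-Za-z][A-Za-z0-9_-]*:", tk) && endsWith(tk, ".")) {
      nxt <- substring(query, ends[i] + 1L, ends[i] + 1L)
      if (!nxt %in% c(",", ")")) {
        out[[length(out) + 1L]] <- substring(tk, 1L, nchar(tk) - 1L)
        out[[length(out) + 1L]] <- "."
        next
      }
    }
    out[[length(out) + 1L]] <- tk
  }
  unlist(out)
}

#' Normalised token sequence of a SPARQL query
#'
#' Whitespace-insensitive tokenisation used to compare two queries for
#' structural equality.
#'
#' @param query SPARQL string
#' @return character vector of tokens
#' @export
sparql_tokens <- function(query) sparql_tokenize(query)

AGG_FUNS <- c("count", "avg", "min", "max")

parse_sparql <- function(query) {
  toks <- sparql_tokenize(query)
  n <- length(toks)
  i <- 1L
  peek <- function() if (i <= n) toks[[i]] else NA_character_
  peek_lc <- function() tolower(peek())
  advance <- function() {
    if (i > n) stop_odsreg("query", "unexpected end of query at token %d", i)
    t <- toks[[i]]
    i <<- i + 1L
    t
  }
  expect <- function(v, what = v) {
    t <- advance()
    if (is.na(t) || tolower(t) != tolower(v))
      stop_odsreg("query", "expected '%s' near token %d ('%s')", what, i - 1L,
                  if (is.na(t)) "<end>" else t)
    t
  }
  prefixes <- STD_PREFIXES
  resolve <- function(tok) {
    if (startsWith(tok, "<")) return(substring(tok, 2L, nchar(tok) - 1L))
    if (tok == "a") return(RDF_TYPE)
    m <- regmatches(tok, regexec("^([A-Za-z][A-Za-z0-9_-]*):(.*)$", tok))[[1]]
    if (length(m) == 3L && m[2] %in% names(prefixes))
      return(paste0(prefixes[[m[2]]], m[3]))
    stop_odsreg("query", "cannot resolve '%s'", tok)
  }
  is_var <- function(tok) !is.na(tok) && startsWith(tok, "?")
  is_literal_tok <- function(tok)
    grepl("^['\"]", tok) || grepl("^[+-]?[0-9]", tok)
  literal_value <- function(tok) {
    if (grepl("^['\"]", tok))
      list(value = substring(tok, 2L, nchar(tok) - 1L), numeric = FALSE)
    else list(value = tok, numeric = TRUE)
  }

  while (peek_lc() == "prefix") {
    advance()
    pn <- advance()
    pfx <- sub(":$", "", pn)
    iri <- advance()
    if (!startsWith(iri, "<")) stop_odsreg("query", "expected IRI after PREFIX")
    prefixes[[pfx]] <- substring(iri, 2L, nchar(iri) - 1L)
  }

  expect("SELECT")
  distinct <- FALSE
  select_items <- list()
  if (peek_lc() == "distinct") { advance(); distinct <- TRUE }
  repeat {
    tk <- peek()
    if (is.na(tk)) stop_odsreg("query", "unexpected end in SELECT list")
    if (tolower(tk) == "where" || tk == "{") break
    if (tk == ",") { advance(); next }
    if (tolower(tk) %in% AGG_FUNS) {
      fun <- tolower(advance())
      expect("(")
      agg_distinct <- FALSE
      if (peek_lc() == "distinct") { advance(); agg_distinct <- TRUE }
      v <- advance()
      if (!is_var(v)) stop_odsreg("query", "aggregate over non-variable")
      expect(")")
      select_items[[length(select_items) + 1L]] <-
        list(kind = "agg", fun = fun, var = substring(v, 2L),
             distinct = agg_distinct)
    } else if (is_var(tk)) {
      advance()
      select_items[[length(select_items) + 1L]] <-
        list(kind = "var", var = substring(tk, 2L))
    } else {
      stop_odsreg("query", "unexpected token '%s' in SELECT list", tk)
    }
  }
  if (peek_lc() == "where") advance()

  patterns <- list()
  filters <- list()
  parse_term <- function() {
    tk <- advance()
    if (is_var(tk)) return(list(kind = "var", name = substring(tk, 2L)))
    if (is_literal_tok(tk)) {
      lit <- literal_value(tk)
      return(list(kind = "literal", value = lit$value, numeric = lit$numeric))
    }
    list(kind = "iri", iri = resolve(tk))
  }
  parse_filter <- function() {
    expect("(")
    tk <- peek()
    if (tolower(tk) == "str") {
      advance(); expect("(")
      v <- advance()
      expect(")")
      op <- advance()
      if (!op %in% c("=", "!=")) stop_odsreg("query", "str() supports = and !=")
      lit <- literal_value(advance())
      filters[[length(filters) + 1L]] <<-
        list(type = "cmp", var = substring(v, 2L), op = op,
             value = lit$value, numeric = FALSE)
    } else if (is_var(tk)) {
      v <- advance()
      op_or_in <- advance()
      if (tolower(op_or_in) == "in") {
        expect("(")
        members <- character(0)
        repeat {
          tk2 <- advance()
          if (tk2 == ")") break
          if (tk2 == ",") next
          members <- c(members, resolve(tk2))
        }
        filters[[length(filters) + 1L]] <<-
          list(type = "in", var = substring(v, 2L), members = members)
        expect(")")
        return(invisible(NULL))
      }
      if (!op_or_in %in% c("=", "!=", "<", "<=", ">", ">="))
        stop_odsreg("query", "unsupported operator '%s'", op_or_in)
      lit <- literal_value(advance())
      filters[[length(filters) + 1L]] <<-
        list(type = "cmp", var = substring(v, 2L), op = op_or_in,
             value = lit$value, numeric = lit$numeric)
    } else {
      stop_odsreg("query", "unsupported FILTER expression near '%s'", tk)
    }
    expect(")")
    invisible(NULL)
  }
  parse_group <- function() {
    expect("{")
    repeat {
      tk <- peek()
      if (is.na(tk)) stop_odsreg("query", "unbalanced braces")
      if (tk == "}") { advance(); break }
      if (tk == ".") { advance(); next }
      if (tk == "{") { parse_group(); next }
      if (tolower(tk) == "filter") { advance(); parse_filter(); next }
      s <- parse_term(); p <- parse_term(); o <- parse_term()
      patterns[[length(patterns) + 1L]] <<- list(s = s, p = p, o = o)
    }
    invisible(NULL)
  }
  parse_group()

  group_by <- NULL
  order_by <- NULL
  while (!is.na(peek())) {
    tk <- tolower(advance())
    if (tk == "group") {
      expect("by")
      v <- advance()
      if (!is_var(v)) stop_odsreg("query", "group by requires a variable")
      group_by <- substring(v, 2L)
    } else if (tk == "order") {
      expect("by")
      desc <- FALSE
      if (peek_lc() %in% c("asc", "desc")) desc <- tolower(advance()) == "desc"
      v <- advance()
      order_by <- list(var = substring(v, 2L), desc = desc)
    } else if (tk == "}") {
      # tolerated stray closing brace after modifiers (as printed queries do)
      next
    } else {
      stop_odsreg("query", "unexpected trailing token '%s'", tk)
    }
  }

  aggs <- Filter(function(x) x$kind == "agg", select_items)
  vars <- vapply(Filter(function(x) x$kind == "var", select_items),
                 `[[`, character(1), "var")
  if (length(aggs) > 0 && !is.null(group_by) && !group_by %in% vars &&
      length(vars) > 0)
    stop_odsreg("query", "group by variable must appear in SELECT")
  list(select = select_items, distinct = distinct, patterns = patterns,
       filters = filters, group_by = group_by, order_by = order_by)
}

# ---- evaluation ----------------------------------------------------------

#' Execute a SPARQL SELECT query over a semantic store
#'
#' Supports the conjunctive SELECT dialect generated by [build_query()]
#' (see file header of the implementation for the exact constructs). Results
#' follow bag semantics; `DISTINCT` deduplicates; aggregation with
#' `group by` yields one row per group. With `ORDER BY` the row order is
#' deterministic (byte order).
#'
#' @param store a `semantic_store`
#' @param query SPARQL SELECT string
#' @return data.frame of variable bindings (column names without `?`);
#'   aggregate columns are named `<fun>_<var>`, e.g. `count_s`
#' @export
execute_sparql <- function(store, query) {
  stopifnot(inherits(store, "semantic_store"))
  q <- parse_sparql(query)
  tr <- data.table::as.data.table(store$triples)

  bindings <- NULL   # data.table of variable bindings
  pending <- q$filters
  apply_ready_filters <- function(b) {
    if (is.null(b)) return(b)
    keep <- rep(TRUE, length(pending))
    for (k in seq_along(pending)) {
      f <- pending[[k]]
      if (!f$var %in% names(b)) next
      col <- b[[f$var]]
      sel <- switch(f$type,
        "in" = col %in% f$members,
        "cmp" = {
          if (f$numeric) {
            x <- suppressWarnings(as.numeric(col))
            v <- as.numeric(f$value)
            switch(f$op, "=" = x == v, "!=" = x != v, "<" = x < v,
                   "<=" = x <= v, ">" = x > v, ">=" = x >= v)
          } else {
            switch(f$op, "=" = col == f$value, "!=" = col != f$value,
                   "<" = col < f$value, "<=" = col <= f$value,
                   ">" = col > f$value, ">=" = col >= f$value)
          }
        })
      sel[is.na(sel)] <- FALSE
      b <- b[sel]
      keep[k] <- FALSE
    }
    pending <<- pending[keep]
    b
  }

  for (pat in q$patterns) {
    cand <- tr
    if (pat$p$kind == "iri") cand <- cand[cand$p == pat$p$iri]
    else if (pat$p$kind != "var")
      stop_odsreg("query", "literal in predicate position")
    if (pat$s$kind == "iri") cand <- cand[cand$s == pat$s$iri]
    if (pat$o$kind == "iri") cand <- cand[cand$o == pat$o$iri & cand$o_kind == "iri"]
    if (pat$o$kind == "literal") cand <- cand[cand$o == pat$o$value &
                                               cand$o_kind == "literal"]
    cols <- list()
    if (pat$s$kind == "var") cols[[pat$s$name]] <- cand$s
    if (pat$p$kind == "var") cols[[pat$p$name]] <- cand$p
    if (pat$o$kind == "var") cols[[pat$o$name]] <- cand$o
    if (length(cols) == 0) {
      if (nrow(cand) == 0) {
        bindings <- data.table::data.table()[0]
        break
      }
      next
    }
    step <- data.table::as.data.table(cols)
    # self-join guard: a pattern like ?x p ?x
    if (anyDuplicated(names(step))) {
      nm <- names(step)
      dupc <- nm[duplicated(nm)][1]
      idx <- which(nm == dupc)
      step <- step[step[[idx[1]]] == step[[idx[2]]], idx[1], with = FALSE]
    }
    if (is.null(bindings)) {
      bindings <- unique(step)
    } else {
      shared <- intersect(names(bindings), names(step))
      if (length(shared) == 0) {
        bindings <- data.table::as.data.table(
          merge.data.frame(bindings, unique(step), by = NULL))
      } else {
        bindings <- merge(bindings, unique(step), by = shared,
                          allow.cartesian = TRUE)
      }
    }
    bindings <- apply_ready_filters(bindings)
    if (nrow(bindings) == 0) break
  }
  if (is.null(bindings)) bindings <- data.table::data.table()
  bindings <- apply_ready_filters(bindings)
  if (length(pending) > 0) {
    # filters over unbound variables match nothing
    bindings <- bindings[0]
  }

  aggs <- Filter(function(x) x$kind == "agg", q$select)
  plain_vars <- vapply(Filter(function(x) x$kind == "var", q$select),
                       `[[`, character(1), "var")

  if (length(aggs) > 0) {
    agg_row <- function(b) {
      vals <- lapply(aggs, function(a) {
        col <- if (a$var %in% names(b)) b[[a$var]] else character(0)
        switch(a$fun,
               count = if (a$distinct) length(unique(col)) else length(col),
               avg = mean(as.numeric(col)),
               min = if (length(col) == 0) NA_real_ else min(as.numeric(col)),
               max = if (length(col) == 0) NA_real_ else max(as.numeric(col)))
      })
      names(vals) <- vapply(aggs, function(a) paste0(a$fun, "_", a$var),
                            character(1))
      vals
    }
    if (is.null(q$group_by)) {
      out <- data.frame(agg_row(bindings), check.names = FALSE)
    } else {
      if (!q$group_by %in% names(bindings) || nrow(bindings) == 0) {
        cols <- c(stats::setNames(list(character(0)), q$group_by),
                  stats::setNames(
                    rep(list(numeric(0)), length(aggs)),
                    vapply(aggs, function(a) paste0(a$fun, "_", a$var),
                           character(1))))
        out <- data.frame(cols, check.names = FALSE,
                          stringsAsFactors = FALSE)
      } else {
        groups <- split(bindings, bindings[[q$group_by]])
        rows <- lapply(sort_c(names(groups)), function(g) {
          data.frame(c(stats::setNames(list(g), q$group_by), agg_row(groups[[g]])),
                     check.names = FALSE, stringsAsFactors = FALSE)
        })
        out <- do.call(rbind, rows)
      }
    }
  } else {
    missing_vars <- setdiff(plain_vars, names(bindings))
    for (v in missing_vars) bindings[[v]] <- character(0)
    out <- as.data.frame(bindings)[, plain_vars, drop = FALSE]
    if (q$distinct) out <- unique(out)
    rownames(out) <- NULL
  }

  if (!is.null(q$order_by) && q$order_by$var %in% names(out)) {
    idx <- order(out[[q$order_by$var]], method = "radix",
                 decreasing = q$order_by$desc)
    out <- out[idx, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
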