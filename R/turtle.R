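# Triple tables and Turtle / N-Triples serialisation.
#
# Triples are held in a plain data.frame with columns:
#   s      subject IRI (character)
#   p      predicate IRI
#   o      object: IRI, or literal lexical form
#   o_kind "iri" or "literal"
#   o_dt   for literals one of "string", "integer", "decimal", "date"; NA for IRIs
#
# The Turtle dialect supported covers what the package itself writes plus the
# common authoring forms: @prefix, prefixed names, <full IRIs>, 'a',
# ';' and ',' continuation, quoted literals with \\-escapes and ^^datatype,
# bare integers/decimals, and '#' comments.

triple_df <- function(s = character(), p = character(), o = character(),
                      o_kind = character(), o_dt = character()) {
  data.frame(s = s, p = p, o = o, o_kind = o_kind, o_dt = o_dt,
             stringsAsFactors = FALSE)
}

empty_triples <- function() {
  triple_df(character(0), character(0), character(0), character(0), character(0))
}

# ---- tokenizer -----------------------------------------------------------

ttl_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  toks <- vector("list", 256L)
  ntok <- 0L
  lines <- cumsum(chars == "\n") + 1L
  push <- function(type, value, at) {
    ntok <<- ntok + 1L
    if (ntok > length(toks)) length(toks) <<- 2L * ntok
    toks[[ntok]] <<- list(type = type, value = value, line = lines[min(at, n)])
  }
  name_end_chars <- c(" ", "\t", "\n", "\r", ";", ",", "<", ">", "\"", "'",
                      "(", ")", "{", "}", "#")
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t", "\n", "\r")) { i <- i + 1L; next }
    if (ch == "#") { while (i <= n && chars[i] != "\n") i <- i + 1L; next }
    if (ch == "<") {
      j <- i + 1L
      while (j <= n && chars[j] != ">") j <- j + 1L
      if (j > n) stop_odsreg("format", "unterminated IRI at line %d", lines[i])
      push("iri", paste0(chars[(i + 1L):(j - 1L)], collapse = ""), i)
      i <- j + 1L
      next
    }
    if (ch == "\"" || ch == "'") {
      q <- ch
      j <- i + 1L
      buf <- character(0)
      while (j <= n && chars[j] != q) {
        if (chars[j] == "\\" && j < n) {
          esc <- chars[j + 1L]
          buf <- c(buf, switch(esc, n = "\n", t = "\t", r = "\r",
                               "\\" = "\\", "\"" = "\"", "'" = "'", esc))
          j <- j + 2L
        } else {
          buf <- c(buf, chars[j])
          j <- j + 1L
        }
      }
      if (j > n) stop_odsreg("format", "unterminated string at line %d", lines[i])
      push("string", paste0(buf, collapse = ""), i)
      i <- j + 1L
      next
    }
    if (ch %in% c(";", ",", "(", ")", "{", "}")) {
      push("punct", ch, i)
      i <- i + 1L
      next
    }
    if (ch == "." &&
        (i == n || chars[i + 1L] %in% c(" ", "\t", "\n", "\r", "#"))) {
      push("punct", ".", i)
      i <- i + 1L
      next
    }
    if (ch == "^" && i < n && chars[i + 1L] == "^") {
      push("punct", "^^", i)
      i <- i + 2L
      next
    }
    if (ch == "@") {
      j <- i + 1L
      while (j <= n && grepl("[A-Za-z-]", chars[j])) j <- j + 1L
      push("keyword", paste0(chars[i:(j - 1L)], collapse = ""), i)
      i <- j
      next
    }
    # name-ish token (prefixed name, bare number, 'a')
    j <- i
    while (j <= n && !(chars[j] %in% name_end_chars)) j <- j + 1L
    tok <- paste0(chars[i:(j - 1L)], collapse = "")
    # a trailing '.' is the statement terminator unless it is a decimal digit tail
    if (endsWith(tok, ".") && !grepl("^[+-]?[0-9]+\\.$", tok)) {
      tok <- substring(tok, 1L, nchar(tok) - 1L)
      push("name", tok, i)
      push("punct", ".", j - 1L)
    } else {
      push("name", tok, i)
    }
    i <- j
  }
  toks[seq_len(ntok)]
}

# ---- parser --------------------------------------------------------------

#' Read a Turtle file into a triple table
#'
#' Parses the Turtle subset used by the package (see file header) and returns
#' the triples together with the prefix map.
#'
#' @param path path to a `.ttl` (or N-Triples) file
#' @return a list with elements `triples` (triple data.frame) and
#'   `prefixes` (named character vector)
#' @export
read_turtle <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  fast <- parse_turtle_lines(lines)
  if (!is.null(fast)) return(fast)
  parse_turtle(paste(lines, collapse = "\n"))
}

# Vectorised fast path for the canonical one-triple-per-line form emitted by
# write_turtle(). Returns NULL when the file uses fuller Turtle syntax.
parse_turtle_lines <- function(lines) {
  lines <- trimws(lines)
  pfx_re <- "^@prefix\\s+([A-Za-z][A-Za-z0-9_-]*):\\s+<([^>]*)>\\s+\\.$"
  is_pfx <- grepl(pfx_re, lines)
  body <- lines[!is_pfx & lines != "" & !startsWith(lines, "#")]
  prefixes <- STD_PREFIXES
  pm <- regmatches(lines[is_pfx], regexec(pfx_re, lines[is_pfx]))
  for (m in pm) prefixes[[m[2]]] <- m[3]
  if (length(body) == 0)
    return(list(triples = empty_triples(), prefixes = prefixes))
  term <- "(<[^>]*>|[A-Za-z][A-Za-z0-9_-]*:[A-Za-z0-9_.-]*|a)"
  objt <- "(<[^>]*>|\"(?:[^\"\\\\]|\\\\.)*\"(?:\\^\\^\\S+)?|[A-Za-z][A-Za-z0-9_-]*:[A-Za-z0-9_.-]*)"
  stmt_re <- paste0("^", term, "\\s+", term, "\\s+", objt, "\\s+\\.$")
  m <- regmatches(body, regexec(stmt_re, body, perl = TRUE))
  if (any(lengths(m) != 4L)) return(NULL)
  mm <- matrix(unlist(m), ncol = 4L, byrow = TRUE)
  res_term <- function(x) {
    out <- x
    is_full <- startsWith(x, "<")
    out[is_full] <- substring(x[is_full], 2L, nchar(x[is_full]) - 1L)
    out[x == "a"] <- RDF_TYPE
    pn <- !is_full & x != "a"
    if (any(pn)) {
      pfx <- sub(":.*$", "", x[pn])
      loc <- sub("^[^:]*:", "", x[pn])
      ns <- prefixes[pfx]
      if (anyNA(ns)) return(NULL)
      out[pn] <- paste0(ns, loc)
    }
    out
  }
  s <- res_term(mm[, 2]); p <- res_term(mm[, 3])
  if (is.null(s) || is.null(p)) return(NULL)
  obj <- mm[, 4]
  is_lit <- startsWith(obj, "\"")
  o <- obj; o_kind <- ifelse(is_lit, "literal", "iri")
  o_dt <- rep(NA_character_, length(obj))
  if (any(!is_lit)) {
    oi <- res_term(obj[!is_lit])
    if (is.null(oi)) return(NULL)
    o[!is_lit] <- oi
  }
  if (any(is_lit)) {
    lex <- sub("\\^\\^\\S+$", "", obj[is_lit])
    lex <- substring(lex, 2L, nchar(lex) - 1L)
    lex <- gsub("\\n", "\n", lex, fixed = TRUE)
    lex <- gsub("\\\"", "\"", lex, fixed = TRUE)
    lex <- gsub("\\\\", "\\", lex, fixed = TRUE)
    dt <- rep("string", sum(is_lit))
    has_dt <- grepl("\\^\\^\\S+$", obj[is_lit])
    dt_tok <- sub("^.*\\^\\^", "", obj[is_lit][has_dt])
    dt_iri <- ifelse(startsWith(dt_tok, "<"),
                     substring(dt_tok, 2L, nchar(dt_tok) - 1L),
                     paste0(XSD_KINDS[["string"]])) # placeholder, fixed below
    pn_dt <- !startsWith(dt_tok, "<")
    if (any(pn_dt)) {
      pfx <- sub(":.*$", "", dt_tok[pn_dt])
      loc <- sub("^[^:]*:", "", dt_tok[pn_dt])
      dt_iri[pn_dt] <- paste0(prefixes[pfx], loc)
    }
    kind <- names(XSD_KINDS)[match(dt_iri, XSD_KINDS)]
    dt[has_dt] <- ifelse(is.na(kind), "string", kind)
    o[is_lit] <- lex
    o_dt[is_lit] <- dt
  }
  list(triples = triple_df(s, p, o, o_kind, o_dt), prefixes = prefixes)
}

parse_turtle <- function(text) {
  toks <- ttl_tokenize(text)
  prefixes <- STD_PREFIXES
  i <- 1L
  nt <- length(toks)
  acc <- vector("list", 64L)
  nacc <- 0L
  addt <- function(df) {
    nacc <<- nacc + 1L
    acc[[nacc]] <<- df
  }
  peek <- function() if (i <= nt) toks[[i]] else NULL
  advance <- function() { t <- toks[[i]]; i <<- i + 1L; t }
  expect_punct <- function(v) {
    t <- advance()
    if (is.null(t) || t$type != "punct" || t$value != v)
      stop_odsreg("format", "expected '%s' at line %d", v,
                  if (is.null(t)) -1L else t$line)
  }
  resolve <- function(tok) {
    if (tok$type == "iri") return(tok$value)
    if (tok$type != "name")
      stop_odsreg("format", "expected IRI or prefixed name at line %d", tok$line)
    v <- tok$value
    if (v == "a") return(RDF_TYPE)
    m <- regmatches(v, regexec("^([A-Za-z][A-Za-z0-9_-]*):(.*)$", v))[[1]]
    if (length(m) == 3L && m[2] %in% names(prefixes))
      return(paste0(prefixes[[m[2]]], m[3]))
    stop_odsreg("format", "cannot resolve name '%s' at line %d", v, tok$line)
  }
  read_object <- function() {
    tok <- advance()
    if (tok$type == "string") {
      dt <- "string"
      nx <- peek()
      if (!is.null(nx) && nx$type == "punct" && nx$value == "^^") {
        advance()
        dt_iri <- resolve(advance())
        k <- names(XSD_KINDS)[match(dt_iri, XSD_KINDS)]
        dt <- if (is.na(k)) "string" else k
      }
      return(list(o = tok$value, o_kind = "literal", o_dt = dt))
    }
    if (tok$type == "name" && grepl("^[+-]?[0-9]+$", tok$value))
      return(list(o = tok$value, o_kind = "literal", o_dt = "integer"))
    if (tok$type == "name" && grepl("^[+-]?[0-9]*\\.[0-9]+$", tok$value))
      return(list(o = tok$value, o_kind = "literal", o_dt = "decimal"))
    list(o = resolve(tok), o_kind = "iri", o_dt = NA_character_)
  }
  while (i <= nt) {
    tok <- peek()
    if (tok$type == "keyword" && tok$value %in% c("@prefix", "@base")) {
      advance()
      if (tok$value == "@prefix") {
        pn <- advance()
        pfx <- sub(":$", "", pn$value)
        iri_tok <- advance()
        if (iri_tok$type != "iri")
          stop_odsreg("format", "expected IRI in @prefix at line %d", iri_tok$line)
        prefixes[[pfx]] <- iri_tok$value
        expect_punct(".")
      } else {
        advance(); expect_punct(".")
      }
      next
    }
    subj <- resolve(advance())
    repeat {
      pred <- resolve(advance())
      repeat {
        obj <- read_object()
        addt(triple_df(subj, pred, obj$o, obj$o_kind, obj$o_dt))
        nx <- peek()
        if (!is.null(nx) && nx$type == "punct" && nx$value == ",") { advance(); next }
        break
      }
      nx <- peek()
      if (!is.null(nx) && nx$type == "punct" && nx$value == ";") { advance(); next }
      break
    }
    expect_punct(".")
  }
  triples <- if (nacc == 0L) empty_triples() else
    do.call(rbind, acc[seq_len(nacc)])
  rownames(triples) <- NULL
  list(triples = triples, prefixes = prefixes)
}

# ---- writer --------------------------------------------------------------

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x
}

# Prefixed form when the local name is simple enough to round-trip; else <iri>.
ttl_term <- function(iri, prefixes) {
  out <- paste0("<", iri, ">")
  for (pfx in names(prefixes)) {
    ns <- prefixes[[pfx]]
    hit <- startsWith(iri, ns)
    local <- substring(iri, nchar(ns) + 1L)
    ok <- hit & grepl("^[A-Za-z_][A-Za-z0-9_-]*$", local)
    out[ok] <- paste0(pfx, ":", local[ok])
  }
  out
}

ttl_object <- function(o, o_kind, o_dt, prefixes) {
  ifelse(o_kind == "iri",
         ttl_term(o, prefixes),
         ifelse(is.na(o_dt) | o_dt == "string",
                paste0("\"", ttl_escape(o), "\""),
                paste0("\"", ttl_escape(o), "\"^^xsd:", o_dt)))
}

#' Write a triple table to a Turtle file
#'
#' Statements are emitted one per line in canonical (byte-sorted) order so
#' that serialisations are diff-stable.
#'
#' @param triples triple data.frame (see [read_turtle()])
#' @param path output file path
#' @param prefixes named character vector of prefix -> namespace
#' @return invisibly, the path
#' @export
write_turtle <- function(triples, path,
                         prefixes = c(ods = DEFAULT_NS, STD_PREFIXES)) {
  lines <- paste0("@prefix ", names(prefixes), ": <", unname(prefixes), "> .")
  if (nrow(triples) > 0) {
    stmt <- paste(ttl_term(triples$s, prefixes),
                  ttl_term(triples$p, prefixes),
                  ttl_object(triples$o, triples$o_kind, triples$o_dt, prefixes),
                  ".")
    lines <- c(lines, "", sort_c(unique(stmt)))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Canonical N-Triples lines for a triple table
#'
#' Full-IRI, byte-sorted, duplicate-free serialisation; used for digesting and
#' round-trip comparison.
#'
#' @param triples triple data.frame
#' @return character vector of N-Triples lines, sorted
#' @export
ntriples_lines <- function(triples) {
  if (nrow(triples) == 0) return(character(0))
  obj <- ifelse(triples$o_kind == "iri",
                paste0("<", triples$o, ">"),
                ifelse(is.na(triples$o_dt) | triples$o_dt == "string",
                       paste0("\"", ttl_escape(triples$o), "\""),
                       paste0("\"", ttl_escape(triples$o), "\"^^<",
                              XSD_KINDS[triples$o_dt], ">")))
  sort_c(unique(paste0("<", triples$s, "> <", triples$p, "> ", obj, " .")))
}
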