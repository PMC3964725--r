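#' @title Filter expressions for protocol requests
#' @description
#' The query protocol supports SQL-like filter criteria built from six
#' comparison operators (`equals`, `like`, `lessThan`, `lessThanOrEquals`,
#' `greaterThan`, `greaterThanOrEquals`), two null checks (`isNull`,
#' `isNotNull`), negation (`not`) and the junctions `and` / `or`. A filter
#' is a finite operator tree that can be evaluated against a unit record
#' and serialized into request documents.
#'
#' Semantics:
#' * A comparison is existential over the record's values at the path: it is
#'   true iff *any* value at the path satisfies it. A comparison on an
#'   absent path is false.
#' * `isNull` is true iff the path is absent from the record; an
#'   empty-string value is a present value.
#' * `like` treats `*` as a multi-character wildcard (the only wildcard).
#' * Ordering comparisons are numeric when both operands parse as decimal
#'   numbers, otherwise lexicographic on Unicode code points.
#' * `equals` is case-sensitive exact string equality.
#' @name filters
NULL

COMPARISON_OPS <- c("equals", "like", "lessThan", "lessThanOrEquals",
                    "greaterThan", "greaterThanOrEquals")
NULLCHECK_OPS <- c("isNull", "isNotNull")
JUNCTION_OPS <- c("and", "or")

#' Validate a concept path
#'
#' Concept paths are slash-separated element paths addressing one concept of
#' the exchange schema (for example an ABCD x-path ending in `.../FileURI`).
#' Comparison is exact string equality.
#'
#' @param path character scalar
#' @return the path, invisibly normalized (no change), or an error
#' @export
concept_path <- function(path) {
  if (!is.character(path) || length(path) != 1L || is.na(path) || !nzchar(path))
    stop("concept path must be a non-empty string", call. = FALSE)
  segs <- strsplit(path, "/", fixed = TRUE)[[1]]
  if (any(grepl("^\\s+$", segs)))
    stop("concept path has a whitespace-only segment: ", path, call. = FALSE)
  path
}

new_filter <- function(kind, op, path = NULL, literal = NULL, children = NULL) {
  structure(list(kind = kind, op = op, path = path, literal = literal,
                 children = children), class = "bcp_filter")
}

#' Filter constructors
#'
#' Build filter-expression nodes. `flt_cmp()` is the general comparison
#' constructor; `flt_equals()` etc. are shorthands. `flt_and()` / `flt_or()`
#' take one or more child filters; `flt_not()` negates a single child.
#'
#' @param op comparison operator, one of `equals`, `like`, `lessThan`,
#'   `lessThanOrEquals`, `greaterThan`, `greaterThanOrEquals`
#' @param path concept path the node refers to
#' @param literal comparison literal (a single string)
#' @param f,... child filter expressions
#' @return an object of class `bcp_filter`
#' @export
flt_cmp <- function(op, path, literal) {
  op <- match.arg(op, COMPARISON_OPS)
  if (!is.character(literal) || length(literal) != 1L || is.na(literal))
    stop("filter literal must be a single string", call. = FALSE)
  new_filter("comparison", op, concept_path(path), literal)
}

#' @rdname flt_cmp
#' @export
flt_equals <- function(path, literal) flt_cmp("equals", path, literal)
#' @rdname flt_cmp
#' @export
flt_like <- function(path, literal) flt_cmp("like", path, literal)
#' @rdname flt_cmp
#' @export
flt_is_null <- function(path) new_filter("nullcheck", "isNull", concept_path(path))
#' @rdname flt_cmp
#' @export
flt_is_not_null <- function(path) new_filter("nullcheck", "isNotNull", concept_path(path))
#' @rdname flt_cmp
#' @export
flt_not <- function(f) {
  stopifnot(inherits(f, "bcp_filter"))
  new_filter("not", "not", children = list(f))
}
#' @rdname flt_cmp
#' @export
flt_and <- function(...) flt_junction("and", list(...))
#' @rdname flt_cmp
#' @export
flt_or <- function(...) flt_junction("or", list(...))

flt_junction <- function(op, children) {
  if (length(children) < 1L)
    stop(op, " needs at least one child filter", call. = FALSE)
  if (!all(vapply(children, inherits, logical(1), "bcp_filter")))
    stop("all children of ", op, " must be filter expressions", call. = FALSE)
  new_filter("junction", op, children = children)
}

#' @export
print.bcp_filter <- function(x, ...) {
  cat("<filter> ", filter_to_text(x), "\n", sep = "")
  invisible(x)
}

# code-point lexicographic comparison, locale independent: -1, 0 or 1
cmp_codepoint <- function(a, b) {
  if (identical(a, b)) return(0L)
  ia <- utf8ToInt(a); ib <- utf8ToInt(b)
  n <- min(length(ia), length(ib))
  if (n > 0L) {
    d <- ia[seq_len(n)] - ib[seq_len(n)]
    i <- which(d != 0L)
    if (length(i)) return(if (d[i[1]] < 0L) -1L else 1L)
  }
  if (length(ia) < length(ib)) -1L else 1L
}

is_decimal_number <- function(x) {
  grepl("^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)$", x)
}

# compare value v against literal l: -1/0/1, numeric when both parse
cmp_values <- function(v, l) {
  if (is_decimal_number(v) && is_decimal_number(l)) {
    nv <- as.numeric(v); nl <- as.numeric(l)
    if (nv < nl) -1L else if (nv > nl) 1L else 0L
  } else {
    cmp_codepoint(v, l)
  }
}

like_match <- function(v, pattern) {
  # '*' is the only wildcard (multi-character); everything else is literal
  parts <- strsplit(pattern, "*", fixed = TRUE)[[1]]
  if (length(parts) == 0L) parts <- ""
  rx <- paste0("^", paste(vapply(parts, function(p)
    gsub("([\\^$.|?*+()\\[\\]{}\\\\])", "\\\\\\1", p, perl = TRUE),
    character(1)), collapse = ".*"))
  if (endsWith(pattern, "*")) rx <- paste0(rx, ".*")
  grepl(paste0(rx, "$"), v, perl = TRUE)
}

#' Evaluate a filter against a unit record
#'
#' Reference semantics of the filter algebra (see [filters]). Total
#' function: never errors on any record/filter pair.
#'
#' @param f a `bcp_filter`
#' @param r a [unit_record()]
#' @return logical scalar
#' @export
evaluate_filter <- function(f, r) {
  stopifnot(inherits(f, "bcp_filter"))
  vals <- r$values[[f$path %||% ""]]
  switch(f$kind,
    comparison = {
      if (is.null(vals)) return(FALSE)
      switch(f$op,
        equals = any(vals == f$literal),
        like = any(vapply(vals, like_match, logical(1), pattern = f$literal)),
        lessThan = any(vapply(vals, function(v) cmp_values(v, f$literal) < 0L, logical(1))),
        lessThanOrEquals = any(vapply(vals, function(v) cmp_values(v, f$literal) <= 0L, logical(1))),
        greaterThan = any(vapply(vals, function(v) cmp_values(v, f$literal) > 0L, logical(1))),
        greaterThanOrEquals = any(vapply(vals, function(v) cmp_values(v, f$literal) >= 0L, logical(1))))
    },
    nullcheck = if (f$op == "isNull") is.null(vals) else !is.null(vals),
    not = !evaluate_filter(f$children[[1]], r),
    junction = {
      hits <- vapply(f$children, evaluate_filter, logical(1), r = r)
      if (f$op == "and") all(hits) else any(hits)
    },
    stop("unknown filter kind: ", f$kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize / parse filter XML fragments
#'
#' The wire form uses the operator name as element name:
#' `<equals path="...">literal</equals>`, `<isNull path="..."/>`,
#' `<not>child</not>`, `<and>children...</and>`. Serialization followed by
#' parsing yields a structurally identical tree.
#'
#' @param f a `bcp_filter`
#' @return `serialize_filter()`: a single XML fragment string;
#'   `parse_filter()`: a `bcp_filter`
#' @export
serialize_filter <- function(f) {
  stopifnot(inherits(f, "bcp_filter"))
  switch(f$kind,
    comparison = sprintf('<%s path="%s">%s</%s>', f$op, xml_esc_attr(f$path),
                         xml_esc_text(f$literal), f$op),
    nullcheck = sprintf('<%s path="%s"/>', f$op, xml_esc_attr(f$path)),
    not = sprintf("<not>%s</not>", serialize_filter(f$children[[1]])),
    junction = sprintf("<%s>%s</%s>", f$op,
                       paste(vapply(f$children, serialize_filter, character(1)),
                             collapse = ""), f$op))
}

#' @rdname serialize_filter
#' @param text XML fragment text
#' @export
parse_filter <- function(text) {
  node <- xml2::xml_root(xml2::read_xml(text))
  parse_filter_node(node)
}

parse_filter_node <- function(node) {
  op <- xml2::xml_name(node)
  if (op %in% COMPARISON_OPS) {
    flt_cmp(op, xml2::xml_attr(node, "path"), xml2::xml_text(node))
  } else if (op %in% NULLCHECK_OPS) {
    p <- concept_path(xml2::xml_attr(node, "path"))
    if (op == "isNull") flt_is_null(p) else flt_is_not_null(p)
  } else if (op == "not") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L) stop("'not' must have exactly one child", call. = FALSE)
    flt_not(parse_filter_node(kids[[1]]))
  } else if (op %in% JUNCTION_OPS) {
    kids <- xml2::xml_children(node)
    flt_junction(op, lapply(kids, parse_filter_node))
  } else {
    stop("unknown filter operator '", op, "'; supported: ",
         paste(c(COMPARISON_OPS, NULLCHECK_OPS, "not", JUNCTION_OPS),
               collapse = ", "), call. = FALSE)
  }
}

#' Compact text form of a filter
#'
#' Filters inside the monitor configuration are written in a compact prefix
#' form, for example `and(isNotNull(/a/b), equals(/a/c,"Abies alba"))`.
#' Grammar: `expr := op '(' args ')'`; comparisons take
#' `(path, "literal")`, null checks `(path)`, `not` one expression,
#' `and`/`or` one or more expressions. Paths are unquoted and may not
#' contain `,`, `(` or `)`; literals are double-quoted with `\"` escaping.
#'
#' @param text filter text
#' @return `parse_filter_text()`: a `bcp_filter`; `filter_to_text()`: text
#' @export
parse_filter_text <- function(text) {
  st <- list(s = text, i = 1L)
  res <- pft_expr(st)
  st <- res$st
  pft_ws(st) -> st
  if (st$i <= nchar(st$s))
    stop("trailing characters in filter text at position ", st$i, call. = FALSE)
  res$f
}

pft_ws <- function(st) {
  while (st$i <= nchar(st$s) && substr(st$s, st$i, st$i) %in% c(" ", "\t")) st$i <- st$i + 1L
  st
}
pft_expect <- function(st, ch) {
  if (st$i > nchar(st$s) || substr(st$s, st$i, st$i) != ch)
    stop("expected '", ch, "' at position ", st$i, " in filter text", call. = FALSE)
  st$i <- st$i + 1L
  st
}
pft_expr <- function(st) {
  st <- pft_ws(st)
  m <- regexpr("^[A-Za-z]+", substr(st$s, st$i, nchar(st$s)))
  if (m == -1L) stop("expected operator at position ", st$i, call. = FALSE)
  op <- substr(st$s, st$i, st$i + attr(m, "match.length") - 1L)
  st$i <- st$i + attr(m, "match.length")
  st <- pft_expect(pft_ws(st), "(")
  if (op %in% COMPARISON_OPS) {
    pr <- pft_path(st); st <- pft_expect(pft_ws(pr$st), ",")
    lr <- pft_string(pft_ws(st)); st <- pft_expect(pft_ws(lr$st), ")")
    list(f = flt_cmp(op, pr$path, lr$value), st = st)
  } else if (op %in% NULLCHECK_OPS) {
    pr <- pft_path(st); st <- pft_expect(pft_ws(pr$st), ")")
    f <- if (op == "isNull") flt_is_null(pr$path) else flt_is_not_null(pr$path)
    list(f = f, st = st)
  } else if (op == "not") {
    cr <- pft_expr(st); st <- pft_expect(pft_ws(cr$st), ")")
    list(f = flt_not(cr$f), st = st)
  } else if (op %in% JUNCTION_OPS) {
    children <- list()
    repeat {
      cr <- pft_expr(st)
      children <- c(children, list(cr$f))
      st <- pft_ws(cr$st)
      ch <- substr(st$s, st$i, st$i)
      if (ch == ",") { st$i <- st$i + 1L } else break
    }
    st <- pft_expect(st, ")")
    list(f = flt_junction(op, children), st = st)
  } else {
    stop("unknown filter operator '", op, "' at position ", st$i, call. = FALSE)
  }
}
pft_path <- function(st) {
  st <- pft_ws(st)
  j <- st$i
  while (j <= nchar(st$s) && !substr(st$s, j, j) %in% c(",", ")", "(")) j <- j + 1L
  path <- trimws(substr(st$s, st$i, j - 1L))
  st$i <- j
  list(path = concept_path(path), st = st)
}
pft_string <- function(st) {
  st <- pft_expect(st, '"')
  out <- character(0)
  repeat {
    if (st$i > nchar(st$s)) stop("unterminated string in filter text", call. = FALSE)
    ch <- substr(st$s, st$i, st$i)
    if (ch == "\\") {
      out <- c(out, substr(st$s, st$i + 1L, st$i + 1L)); st$i <- st$i + 2L
    } else if (ch == '"') {
      st$i <- st$i + 1L
      return(list(value = paste(out, collapse = ""), st = st))
    } else {
      out <- c(out, ch); st$i <- st$i + 1L
    }
  }
}

#' @rdname parse_filter_text
#' @param f a `bcp_filter`
#' @export
filter_to_text <- function(f) {
  stopifnot(inherits(f, "bcp_filter"))
  switch(f$kind,
    comparison = sprintf('%s(%s,"%s")', f$op, f$path,
                         gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", f$literal))),
    nullcheck = sprintf("%s(%s)", f$op, f$path),
    not = sprintf("not(%s)", filter_to_text(f$children[[1]])),
    junction = sprintf("%s(%s)", f$op,
                       paste(vapply(f$children, filter_to_text, character(1)),
                             collapse = ", ")))
}

# XML escaping helpers (deterministic byte output)
xml_esc_text <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
xml_esc_attr <- function(x) {
  x <- xml_esc_text(x)
  x <- gsub('"', "&quot;", x, fixed = TRUE)
  gsub("\n", "&#10;", x, fixed = TRUE)
}
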