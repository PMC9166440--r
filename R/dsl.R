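# Text DSL for retrieval rules.
#
#   query  := OR(q; q; ...) | AND(q; q; ...) | SPAN(...) | "a phrase" | term
#   SPAN(groups=[t1|t2, t3|t4]; window=10; not=[no,not]; ordered=false;
#        scope=match)
#
# Rule files are line-based: `axis:` and `default:` headers followed by one
# `label: query` rule per line; lines starting with # are comments.

new_scanner <- function(text) {
  s <- new.env(parent = emptyenv())
  s$text <- text
  s$chars <- strsplit(text, "", fixed = TRUE)[[1]]
  s$pos <- 1L
  s$n <- length(s$chars)
  s
}

scan_fail <- function(s, what) {
  stop(sprintf("query parse error at character %d: %s (near %s)", s$pos, what,
               dQuote(substr(s$text, s$pos, min(s$n, s$pos + 15L)))),
       call. = FALSE)
}

skip_ws <- function(s) {
  while (s$pos <= s$n && s$chars[s$pos] %in% c(" ", "\t")) s$pos <- s$pos + 1L
}

scan_peek <- function(s) if (s$pos <= s$n) s$chars[s$pos] else ""

scan_expect <- function(s, ch) {
  skip_ws(s)
  if (scan_peek(s) != ch) scan_fail(s, paste0("expected '", ch, "'"))
  s$pos <- s$pos + 1L
}

scan_word <- function(s) {
  skip_ws(s)
  start <- s$pos
  while (s$pos <= s$n && grepl("[A-Za-z0-9_]", s$chars[s$pos])) {
    s$pos <- s$pos + 1L
  }
  if (s$pos == start) scan_fail(s, "expected a term")
  paste(s$chars[start:(s$pos - 1L)], collapse = "")
}

scan_quoted <- function(s) {
  scan_expect(s, '"')
  start <- s$pos
  while (s$pos <= s$n && s$chars[s$pos] != '"') s$pos <- s$pos + 1L
  if (s$pos > s$n) scan_fail(s, "unterminated phrase quote")
  phrase <- paste(s$chars[start:(s$pos - 1L)], collapse = "")
  s$pos <- s$pos + 1L
  if (!nzchar(trimws(phrase))) scan_fail(s, "empty phrase")
  phrase
}

#' Parse a query from its text form
#'
#' @param text a single query expression in the rule DSL, e.g.
#'   `OR("ct chest"; "ct of the chest")` or
#'   `SPAN(groups=[worrisome|concerning, recurrence]; window=10;
#'   not=[no,not])`.
#' @return a query object.
#' @seealso [format_query()], [load_rules()]
#' @export
#' @examples
#' parse_query('OR("chest x ray"; "chest radiograph")')
parse_query <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- new_scanner(text)
  q <- parse_expr(s)
  skip_ws(s)
  if (s$pos <= s$n) scan_fail(s, "unexpected trailing input")
  q
}

parse_expr <- function(s) {
  skip_ws(s)
  if (scan_peek(s) == '"') return(phrase_query(scan_quoted(s)))
  word <- scan_word(s)
  upper <- toupper(word)
  skip_ws(s)
  if (upper %in% c("OR", "AND") && scan_peek(s) == "(") {
    s$pos <- s$pos + 1L
    children <- list(parse_expr(s))
    skip_ws(s)
    while (scan_peek(s) == ";") {
      s$pos <- s$pos + 1L
      children[[length(children) + 1L]] <- parse_expr(s)
      skip_ws(s)
    }
    scan_expect(s, ")")
    return(bool_query(upper, children))
  }
  if (upper == "SPAN" && scan_peek(s) == "(") {
    s$pos <- s$pos + 1L
    return(parse_span_body(s))
  }
  phrase_query(word)
}

parse_span_body <- function(s) {
  args <- list(window = 10L, negation_terms = c("no", "not"),
               ordered = FALSE, negation_scope = "match")
  groups <- NULL
  repeat {
    skip_ws(s)
    key <- tolower(scan_word(s))
    scan_expect(s, "=")
    if (key == "groups") {
      groups <- parse_group_list(s)
    } else if (key == "window") {
      w <- scan_word(s)
      if (!grepl("^[0-9]+$", w)) scan_fail(s, "window must be an integer")
      args$window <- as.integer(w)
    } else if (key == "not") {
      args$negation_terms <- parse_term_list(s)
    } else if (key == "ordered") {
      v <- tolower(scan_word(s))
      if (!v %in% c("true", "false")) {
        scan_fail(s, "ordered must be true or false")
      }
      args$ordered <- v == "true"
    } else if (key == "scope") {
      v <- tolower(scan_word(s))
      if (!v %in% c("match", "document")) {
        scan_fail(s, "scope must be match or document")
      }
      args$negation_scope <- v
    } else {
      scan_fail(s, paste0("unknown SPAN argument '", key, "'"))
    }
    skip_ws(s)
    ch <- scan_peek(s)
    if (ch == ";") { s$pos <- s$pos + 1L; next }
    if (ch == ")") { s$pos <- s$pos + 1L; break }
    scan_fail(s, "expected ';' or ')' in SPAN(...)")
  }
  if (is.null(groups)) scan_fail(s, "SPAN requires groups=[...]")
  span_query(groups, window = args$window,
             negation_terms = args$negation_terms, ordered = args$ordered,
             negation_scope = args$negation_scope)
}

parse_group_list <- function(s) {
  scan_expect(s, "[")
  groups <- list()
  repeat {
    g <- scan_word(s)
    skip_ws(s)
    while (scan_peek(s) == "|") {
      s$pos <- s$pos + 1L
      g <- c(g, scan_word(s))
      skip_ws(s)
    }
    groups[[length(groups) + 1L]] <- g
    ch <- scan_peek(s)
    if (ch == ",") { s$pos <- s$pos + 1L; next }
    if (ch == "]") { s$pos <- s$pos + 1L; break }
    scan_fail(s, "expected ',' or ']' in groups=[...]")
  }
  groups
}

parse_term_list <- function(s) {
  scan_expect(s, "[")
  skip_ws(s)
  if (scan_peek(s) == "]") { s$pos <- s$pos + 1L; return(character()) }
  terms <- scan_word(s)
  skip_ws(s)
  while (scan_peek(s) == ",") {
    s$pos <- s$pos + 1L
    terms <- c(terms, scan_word(s))
    skip_ws(s)
  }
  scan_expect(s, "]")
  terms
}

#' Serialize a query to its canonical text form
#'
#' `parse_query(format_query(q))` reproduces `q` exactly for every query
#' the DSL can express.
#'
#' @param q a query object.
#' @return a single string in the rule DSL.
#' @export
format_query <- function(q) {
  if (inherits(q, "phrase_query")) {
    if (length(q$phrase) == 1L) return(q$phrase)
    return(paste0('"', paste(q$phrase, collapse = " "), '"'))
  }
  if (inherits(q, "span_query")) {
    groups <- paste(vapply(q$term_groups, paste, "", collapse = "|"),
                    collapse = ", ")
    return(sprintf(
      "SPAN(groups=[%s]; window=%d; not=[%s]; ordered=%s; scope=%s)",
      groups, q$window, paste(q$negation_terms, collapse = ","),
      tolower(as.character(q$ordered)), q$negation_scope))
  }
  if (inherits(q, "bool_query")) {
    return(sprintf("%s(%s)", q$operator,
                   paste(vapply(q$children, format_query, ""),
                         collapse = "; ")))
  }
  stop("unknown query node type: ", paste(class(q), collapse = "/"),
       call. = FALSE)
}

#' Construct a rule set
#'
#' A rule set maps classification labels of one annotation axis to queries.
#' Rule order matters: when a report fires more than one rule, the first
#' listed label wins (and the conflict is surfaced by [classify_axis()]).
#' Rules are pure functions of the report text; no metadata is consulted.
#'
#' @param axis `"image_type"`, `"indication"` or `"findings"`.
#' @param rules named list of query objects; names are labels from the
#'   axis vocabulary.
#' @param default_label label applied when no rule fires.
#' @return an object of class `rule_set`.
#' @export
rule_set <- function(axis, rules, default_label) {
  axis <- match.arg(axis, ANNOTATION_AXES)
  vocab <- axis_labels(axis)
  if (!is.list(rules) || is.null(names(rules)) ||
      any(!nzchar(names(rules)))) {
    stop("rules must be a named list of queries", call. = FALSE)
  }
  bad <- setdiff(names(rules), vocab)
  if (length(bad)) {
    stop(sprintf("label(s) not in %s vocabulary: %s", axis,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(names(rules))) {
    stop("duplicate rule label(s)", call. = FALSE)
  }
  if (!all(vapply(rules, inherits, logical(1), "query"))) {
    stop("every rule must be a query object", call. = FALSE)
  }
  if (!default_label %in% vocab) {
    stop(sprintf("default label '%s' not in %s vocabulary", default_label,
                 axis), call. = FALSE)
  }
  structure(list(axis = axis, rules = rules, default_label = default_label),
            class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule_set> axis=%s, %d rule(s), default=%s\n", x$axis,
              length(x$rules), x$default_label))
  for (lbl in names(x$rules)) {
    cat(sprintf("  %s: %s\n", lbl, format_query(x$rules[[lbl]])))
  }
  invisible(x)
}

#' Load a rule set from a config file
#'
#' @param path path to a rule file: `axis:` and `default:` headers, then one
#'   `label: query` line per rule (queries in the DSL of [parse_query()]);
#'   `#` lines are comments. Parse errors name the file and line.
#' @return a `rule_set`.
#' @seealso [default_rules()] for the shipped rule files.
#' @export
load_rules <- function(path) {
  if (!file.exists(path)) stop("no such rule file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  axis <- NULL; default_label <- NULL
  labels <- character(); queries <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line) || startsWith(line, "#")) next
    m <- regmatches(line, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", line))[[1]]
    if (length(m) != 3L) {
      stop(sprintf("%s:%d: expected 'key: value' or 'label: query'",
                   path, ln), call. = FALSE)
    }
    key <- m[2]; value <- m[3]
    if (key == "axis") {
      axis <- value
    } else if (key == "default") {
      default_label <- value
    } else {
      if (is.null(axis)) {
        stop(sprintf("%s:%d: 'axis:' header must precede rules", path, ln),
             call. = FALSE)
      }
      q <- tryCatch(parse_query(value), error = function(e) {
        stop(sprintf("%s:%d: %s", path, ln, conditionMessage(e)),
             call. = FALSE)
      })
      labels <- c(labels, key)
      queries[[key]] <- q
    }
  }
  if (is.null(axis)) stop(path, ": missing 'axis:' header", call. = FALSE)
  if (is.null(default_label)) {
    stop(path, ": missing 'default:' header", call. = FALSE)
  }
  rule_set(axis, queries[labels], default_label)
}

#' Write a rule set to a config file
#' @param rules a `rule_set`.
#' @param path output path.
#' @return (invisibly) `path`.
#' @export
write_rules <- function(rules, path) {
  stopifnot(inherits(rules, "rule_set"))
  lines <- c(sprintf("axis: %s", rules$axis),
             sprintf("default: %s", rules$default_label),
             vapply(names(rules$rules), function(lbl) {
               sprintf("%s: %s", lbl, format_query(rules$rules[[lbl]]))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Shipped default rule sets
#'
#' The package ships one editable rule file per axis under
#' `system.file("rules", package = "radsift")`. They follow the structure
#' used in rule-based radiology abstraction: per-image-type phrase queries
#' combined by OR; a phrase query for the surveillance indication; and
#' two-group span queries (hedge term + disease term within a 10-token
#' window, negated by "no"/"not") for suspicious and definitive recurrence
#' findings. The term lists are deliberately small, plain-language
#' approximations meant to be edited for a local report corpus.
#'
#' @param axis `"image_type"`, `"indication"` or `"findings"`.
#' @return a `rule_set`.
#' @export
default_rules <- function(axis = c("image_type", "indication", "findings")) {
  axis <- match.arg(axis)
  path <- system.file("rules", paste0(axis, ".rules"), package = "radsift")
  if (!nzchar(path)) stop("shipped rule file not found for axis ", axis)
  load_rules(path)
}
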