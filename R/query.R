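#' Phrase query
#'
#' Matches a contiguous run of tokens. Matching is over normalized tokens,
#' so it is case- and punctuation-insensitive ("PA and lateral" matches
#' "PA AND LATERAL"). A single-word phrase behaves as a plain term query.
#'
#' @param phrase either a single string (tokenized internally) or a
#'   character vector of tokens; at least one token.
#' @return a query object of class `c("phrase_query", "query")`.
#' @export
#' @examples
#' phrase_query("ct of the chest")
phrase_query <- function(phrase) {
  if (length(phrase) == 1L) phrase <- tokenize(phrase)$normalized
  phrase <- tolower(as.character(phrase))
  if (length(phrase) < 1L || any(!nzchar(phrase))) {
    stop("phrase_query needs at least one non-empty token", call. = FALSE)
  }
  structure(list(phrase = phrase),
            class = c("phrase_query", "query"))
}

#' Span query with negation exclusion
#'
#' A span query fires where at least one term from *each* term group occurs
#' within a bounded token window ("within a 10-word span"). A candidate span
#' is invalidated when a negation token ("no", "not" by default) falls
#' within the same window-width neighbourhood of the matched terms, so
#' "no findings concerning for recurrence" is excluded while "findings
#' concerning for recurrence" matches. See [match_span()] for the exact
#' semantics.
#'
#' @param term_groups list (length >= 2) of character vectors; a match needs
#'   one term from each group. Terms are normalized to lower case.
#' @param window maximum width of the matching span in tokens, first hit to
#'   last hit inclusive; must be at least the number of groups. Default 10.
#' @param negation_terms tokens that invalidate a span (default
#'   `c("no", "not")`).
#' @param ordered if `TRUE`, group hits must occur in group order.
#' @param negation_scope `"match"` (default): only the negated span is
#'   discarded, other valid spans in the document still count. `"document"`:
#'   any negated span excludes the whole document from retrieval — the
#'   strict reading of "those reports were excluded".
#' @return a query object of class `c("span_query", "query")`.
#' @export
#' @examples
#' span_query(list(c("worrisome", "concerning"), c("recurrence")), window = 10)
span_query <- function(term_groups, window = 10L,
                       negation_terms = c("no", "not"),
                       ordered = FALSE,
                       negation_scope = c("match", "document")) {
  negation_scope <- match.arg(negation_scope)
  if (!is.list(term_groups) || length(term_groups) < 2L) {
    stop("span_query needs at least two term groups", call. = FALSE)
  }
  term_groups <- lapply(term_groups, function(g) {
    g <- tolower(as.character(g))
    if (!length(g) || any(!nzchar(g))) {
      stop("every term group must contain at least one non-empty term",
           call. = FALSE)
    }
    unique(g)
  })
  window <- as.integer(window)
  if (is.na(window) || window < length(term_groups)) {
    stop("window must be a positive integer >= number of term groups",
         call. = FALSE)
  }
  structure(list(term_groups = term_groups, window = window,
                 negation_terms = unique(tolower(as.character(negation_terms))),
                 ordered = isTRUE(ordered),
                 negation_scope = negation_scope),
            class = c("span_query", "query"))
}

#' Boolean query
#'
#' Set algebra over per-document match results: `OR` retrieves the union of
#' its children's document sets, `AND` the intersection.
#'
#' @param operator `"AND"` or `"OR"`.
#' @param children list (length >= 1) of query objects.
#' @return a query object of class `c("bool_query", "query")`.
#' @export
bool_query <- function(operator = c("OR", "AND"), children) {
  operator <- match.arg(toupper(operator), c("OR", "AND"))
  if (!is.list(children) || length(children) < 1L ||
      !all(vapply(children, inherits, logical(1), "query"))) {
    stop("children must be a non-empty list of query objects", call. = FALSE)
  }
  structure(list(operator = operator, children = children),
            class = c("bool_query", "query"))
}

#' @rdname bool_query
#' @param ... child queries.
#' @export
or_query <- function(...) bool_query("OR", list(...))

#' @rdname bool_query
#' @export
and_query <- function(...) bool_query("AND", list(...))

#' @export
print.query <- function(x, ...) {
  cat(format_query(x), "\n")
  invisible(x)
}

# All positive terms a query can match (negation terms excluded); used for
# candidate-document lookup in the index.
query_terms <- function(q) {
  if (inherits(q, "phrase_query")) return(q$phrase)
  if (inherits(q, "span_query")) return(unique(unlist(q$term_groups)))
  if (inherits(q, "bool_query")) {
    return(unique(unlist(lapply(q$children, query_terms))))
  }
  stop("unknown query node type: ", paste(class(q), collapse = "/"),
       call. = FALSE)
}

#' Find phrase occurrences in a token stream
#'
#' @param tokens a `token_stream` (from [tokenize()]) or a character vector
#'   of normalized tokens.
#' @param q a `phrase_query`.
#' @return data.frame with token-position columns `start`, `end` (1-based,
#'   inclusive), one row per occurrence.
#' @export
match_phrase <- function(tokens, q) {
  norm <- normalized_tokens(tokens)
  k <- length(q$phrase)
  n <- length(norm)
  if (n < k) return(empty_spans())
  cand <- which(norm == q$phrase[1L])
  cand <- cand[cand + k - 1L <= n]
  if (k > 1L) {
    for (j in 2L:k) {
      cand <- cand[norm[cand + j - 1L] == q$phrase[j]]
      if (!length(cand)) break
    }
  }
  data.frame(start = cand, end = cand + k - 1L)
}

normalized_tokens <- function(tokens) {
  if (is.data.frame(tokens)) tokens$normalized else tolower(as.character(tokens))
}

empty_spans <- function() data.frame(start = integer(), end = integer())

#' Find valid span-query matches in a token stream
#'
#' Semantics: a *covering span* is a token interval containing at least one
#' hit from every term group (in group order when `ordered = TRUE`). Matches
#' are the minimal (non-extendable) covering spans whose width does not
#' exceed `window`. A candidate span `[a, b]` is invalidated by a negation
#' token at position `p` whenever the negation could share a `window`-wide
#' span with the matched terms, i.e. `max(b, p) - min(a, p) + 1 <= window`;
#' this is what excludes "no findings concerning for recurrence" even though
#' "no" sits outside the minimal span itself. With
#' `negation_scope = "document"`, one invalidated candidate suppresses every
#' match in the stream.
#'
#' @param tokens a `token_stream` or character vector of normalized tokens.
#' @param q a `span_query`.
#' @return data.frame with columns `start`, `end` (token positions) of valid
#'   minimal spans; zero rows when nothing matches.
#' @export
#' @examples
#' toks <- tokenize("findings concerning for recurrence of malignancy")
#' q <- span_query(list(c("concerning", "worrisome"), "recurrence"))
#' match_span(toks, q)
#' match_span(tokenize("no findings concerning for recurrence"), q)
match_span <- function(tokens, q) {
  norm <- normalized_tokens(tokens)
  n <- length(norm)
  if (n == 0L) return(empty_spans())
  hits <- lapply(q$term_groups, function(g) which(norm %in% g))
  if (any(!lengths(hits))) return(empty_spans())
  ends <- minimal_cover_ends(hits, n, q$ordered)
  a <- which(!is.na(ends))
  if (!length(a)) return(empty_spans())
  b <- ends[a]
  # keep minimal spans: for each distinct end, the latest start
  keep <- !duplicated(b, fromLast = TRUE)
  a <- a[keep]; b <- b[keep]
  ok_width <- (b - a + 1L) <= q$window
  a <- a[ok_width]; b <- b[ok_width]
  if (!length(a)) return(empty_spans())
  neg <- which(norm %in% q$negation_terms)
  if (length(neg)) {
    negated <- vapply(seq_along(a), function(i) {
      any(pmax(b[i], neg) - pmin(a[i], neg) + 1L <= q$window)
    }, logical(1))
    if (q$negation_scope == "document" && any(negated)) return(empty_spans())
    a <- a[!negated]; b <- b[!negated]
  }
  data.frame(start = a, end = b)
}

# For each start position a, the minimal end b such that [a, b] contains a
# hit from every group (respecting order when ordered). NA when impossible.
minimal_cover_ends <- function(hits, n, ordered) {
  ends <- rep(NA_integer_, n)
  if (!ordered) {
    for (a in seq_len(n)) {
      b <- a
      ok <- TRUE
      for (h in hits) {
        i <- h[h >= a]
        if (!length(i)) { ok <- FALSE; break }
        if (i[1L] > b) b <- i[1L]
      }
      if (!ok) break  # exhausted for all later starts too
      ends[a] <- b
    }
  } else {
    for (a in seq_len(n)) {
      p <- a - 1L
      ok <- TRUE
      first <- TRUE
      for (h in hits) {
        i <- if (first) h[h >= a] else h[h > p]
        if (!length(i)) { ok <- FALSE; break }
        p <- i[1L]
        first <- FALSE
      }
      if (ok) ends[a] <- p
    }
  }
  ends
}

# Evaluate any query against one normalized token vector, returning the
# matching spans (possibly empty). Boolean AND requires all children to
# match; its spans are the union of child spans. Used by execute_query()
# after index-based candidate pruning.
eval_query_tokens <- function(norm, q) {
  if (inherits(q, "phrase_query")) return(match_phrase(norm, q))
  if (inherits(q, "span_query")) return(match_span(norm, q))
  if (inherits(q, "bool_query")) {
    child_spans <- lapply(q$children, eval_query_tokens, norm = norm)
    matched <- vapply(child_spans, nrow, integer(1)) > 0L
    hit <- if (q$operator == "OR") any(matched) else all(matched)
    if (!hit) return(empty_spans())
    out <- unique(do.call(rbind, child_spans[matched]))
    return(out[order(out$start, out$end), , drop = FALSE])
  }
  stop("unknown query node type: ", paste(class(q), collapse = "/"),
       call. = FALSE)
}
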