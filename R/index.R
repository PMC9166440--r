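#' Build an inverted index over a corpus
#'
#' Tokenizes every report (document title and body are concatenated, so a
#' query sees the entire scope of the document) and builds term -> postings
#' of `(doc_id, token positions)`. The tokenized streams are cached on the
#' index so query execution never re-tokenizes.
#'
#' @param corpus a `report_corpus`.
#' @return an object of class `report_index`.
#' @export
build_index <- function(corpus) {
  stopifnot(inherits(corpus, "report_corpus"))
  docs <- corpus$documents
  streams <- vector("list", nrow(docs))
  for (i in seq_len(nrow(docs))) {
    streams[[i]] <- tokenize(full_text(docs$title[i], docs$text[i]))
  }
  names(streams) <- docs$doc_id
  norm <- lapply(streams, `[[`, "normalized")
  lens <- lengths(norm)
  postings <- new.env(parent = emptyenv(), hash = TRUE)
  if (sum(lens)) {
    flat <- data.frame(
      doc = rep(docs$doc_id, lens),
      term = unlist(norm, use.names = FALSE),
      pos = unlist(lapply(lens, seq_len), use.names = FALSE),
      stringsAsFactors = FALSE)
    by_term <- split(seq_len(nrow(flat)), flat$term)
    for (term in names(by_term)) {
      idx <- by_term[[term]]
      assign(term, split(flat$pos[idx], flat$doc[idx]), envir = postings)
    }
  }
  structure(list(doc_ids = docs$doc_id, streams = streams,
                 postings = postings, n_tokens = sum(lens)),
            class = "report_index")
}

#' @export
print.report_index <- function(x, ...) {
  cat(sprintf("<report_index> %d documents, %d tokens, %d distinct terms\n",
              length(x$doc_ids), x$n_tokens,
              length(ls(x$postings, sorted = FALSE))))
  invisible(x)
}

#' Postings for one term
#' @param index a `report_index`.
#' @param term a normalized token.
#' @return named list: `doc_id` -> integer vector of token positions
#'   (empty list when the term is absent).
#' @export
term_postings <- function(index, term) {
  if (exists(term, envir = index$postings, inherits = FALSE)) {
    get(term, envir = index$postings, inherits = FALSE)
  } else {
    structure(list(), names = character())
  }
}

docs_with_term <- function(index, term) names(term_postings(index, term))

docs_with_any <- function(index, terms) {
  unique(unlist(lapply(terms, docs_with_term, index = index),
                use.names = FALSE))
}

# Candidate documents that could possibly match q; every true match is a
# candidate (phrase: docs containing all phrase tokens; span: docs
# containing >= 1 term of each group; boolean: set algebra on candidates).
candidate_docs <- function(index, q) {
  if (inherits(q, "phrase_query")) {
    return(Reduce(intersect, lapply(unique(q$phrase), docs_with_term,
                                    index = index)))
  }
  if (inherits(q, "span_query")) {
    return(Reduce(intersect, lapply(q$term_groups, docs_with_any,
                                    index = index)))
  }
  if (inherits(q, "bool_query")) {
    sets <- lapply(q$children, candidate_docs, index = index)
    op <- if (q$operator == "OR") union else intersect
    return(Reduce(op, sets))
  }
  stop("unknown query node type: ", paste(class(q), collapse = "/"),
       call. = FALSE)
}

#' Execute a query against an indexed corpus
#'
#' Pure Boolean retrieval (no ranking): `OR` is the union and `AND` the
#' intersection of the children's retrieved sets; phrase and span queries
#' retrieve the documents where their matcher finds at least one valid
#' (non-negated) span. The index is used only to prune candidates; matching
#' itself runs on the cached token streams, so results are identical to a
#' per-document scan.
#'
#' @param index a `report_index` built over the corpus being queried.
#' @param q a query object.
#' @return an object of class `query_result`: list with `doc_ids` (sorted
#'   character vector) and `spans` (named list, one data.frame of token
#'   `start`/`end` spans per retrieved doc).
#' @export
execute_query <- function(index, q) {
  stopifnot(inherits(index, "report_index"), inherits(q, "query"))
  cand <- candidate_docs(index, q)
  spans <- list()
  for (d in cand) {
    s <- eval_query_tokens(index$streams[[d]]$normalized, q)
    if (nrow(s)) spans[[d]] <- s
  }
  ids <- if (length(spans)) sort(names(spans)) else character(0)
  structure(list(doc_ids = ids, spans = spans[ids]), class = "query_result")
}

#' @export
print.query_result <- function(x, ...) {
  cat(sprintf("<query_result> %d documents retrieved\n", length(x$doc_ids)))
  if (length(x$doc_ids)) {
    cat("  ", paste(utils::head(x$doc_ids, 8L), collapse = ", "),
        if (length(x$doc_ids) > 8L) "..." else "", "\n")
  }
  invisible(x)
}

#' One-call search over a corpus
#' @param corpus a `report_corpus`.
#' @param q a query object.
#' @param index optional pre-built `report_index` over the same corpus.
#' @return a `query_result` (see [execute_query()]).
#' @export
search_corpus <- function(corpus, q, index = NULL) {
  if (is.null(index)) index <- build_index(corpus)
  execute_query(index, q)
}
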