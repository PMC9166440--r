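#' Build a highlighted snippet for a document's matches
#'
#' Produces the abstractor-facing view of a retrieval hit: a window of text
#' around each match with character offsets for highlighting. Overlapping
#' context windows are merged; non-adjacent windows are joined with
#' `" ... "` in the window text. Highlight offsets always refer to the full
#' searched text (title and body concatenated with a newline), so callers
#' can paint them onto the original document.
#'
#' @param doc one row of `corpus$documents` (or any list with `doc_id`,
#'   `title`, `text`).
#' @param match_spans data.frame of token `start`/`end` spans, as returned
#'   in a [execute_query()] result.
#' @param context_tokens number of tokens of context either side (default 5).
#' @param terms optional character vector of query terms; when given, only
#'   occurrences of those terms inside each match span are highlighted,
#'   otherwise the whole span is.
#' @return an object of class `snippet`: list with `doc_id`, `window_text`,
#'   `highlight_spans` (data.frame of `char_start`, `char_end`) and
#'   `windows` (merged token windows).
#' @export
make_snippet <- function(doc, match_spans, context_tokens = 5L,
                         terms = NULL) {
  stream <- tokenize(full_text(doc$title, doc$text))
  n <- nrow(stream)
  if (!nrow(match_spans)) {
    stop("no match spans supplied for doc ", doc$doc_id, call. = FALSE)
  }
  if (any(match_spans$start < 1L) || any(match_spans$end > n) ||
      any(match_spans$start > match_spans$end)) {
    stop("match span outside document ", doc$doc_id, call. = FALSE)
  }
  ms <- match_spans[order(match_spans$start, match_spans$end), , drop = FALSE]
  win <- data.frame(start = pmax(1L, ms$start - context_tokens),
                    end = pmin(n, ms$end + context_tokens))
  merged <- win[1, , drop = FALSE]
  if (nrow(win) > 1L) {
    for (i in 2:nrow(win)) {
      last <- nrow(merged)
      if (win$start[i] <= merged$end[last] + 1L) {
        merged$end[last] <- max(merged$end[last], win$end[i])
      } else {
        merged <- rbind(merged, win[i, ])
      }
    }
  }
  text <- full_text(doc$title, doc$text)
  pieces <- substring(text, stream$char_start[merged$start],
                      stream$char_end[merged$end])
  if (is.null(terms)) {
    hl <- data.frame(char_start = stream$char_start[ms$start],
                     char_end = stream$char_end[ms$end])
  } else {
    terms <- tolower(terms)
    idx <- unique(unlist(lapply(seq_len(nrow(ms)), function(i) {
      rng <- ms$start[i]:ms$end[i]
      rng[stream$normalized[rng] %in% terms]
    })))
    idx <- sort(idx)
    hl <- data.frame(char_start = stream$char_start[idx],
                     char_end = stream$char_end[idx])
  }
  structure(list(doc_id = doc$doc_id,
                 window_text = paste(pieces, collapse = " ... "),
                 highlight_spans = hl,
                 windows = merged),
            class = "snippet")
}

#' @export
print.snippet <- function(x, ...) {
  cat(sprintf("<snippet> %s (%d highlight(s))\n", x$doc_id,
              nrow(x$highlight_spans)))
  cat(" ", x$window_text, "\n")
  invisible(x)
}
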