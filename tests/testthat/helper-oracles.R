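# Independent brute-force oracles and random generators used by the
# property tests. Nothing here touches the package's index or matching
# internals: documents are evaluated by direct enumeration.

# All covering spans [a, b]: at least one hit of every group inside (in
# group order when ordered), found by exhaustive enumeration.
oracle_covering_spans <- function(norm, groups, ordered = FALSE) {
  n <- length(norm)
  out <- list()
  covers <- function(a, b) {
    if (!ordered) {
      return(all(vapply(groups, function(g) any(norm[a:b] %in% g),
                        logical(1))))
    }
    p <- a - 1L
    for (gi in seq_along(groups)) {
      idx <- which(norm %in% groups[[gi]])
      idx <- idx[idx <= b & idx > p & (gi > 1L | idx >= a)]
      if (!length(idx)) return(FALSE)
      p <- idx[1L]
    }
    TRUE
  }
  for (a in seq_len(n)) {
    for (b in a:n) {
      if (covers(a, b)) out[[length(out) + 1L]] <- c(a, b)
    }
  }
  out
}

# Reference implementation of span matching: minimal covering spans of
# width <= window, discarding spans with a negation token within the same
# window-width neighbourhood; "document" scope suppresses everything when
# any width-eligible candidate is negated.
oracle_match_span <- function(norm, q) {
  empty <- data.frame(start = integer(), end = integer())
  if (!length(norm)) return(empty)
  cov <- oracle_covering_spans(norm, q$term_groups, q$ordered)
  if (!length(cov)) return(empty)
  minimal <- Filter(function(s) {
    !any(vapply(cov, function(t) {
      t[1] >= s[1] && t[2] <= s[2] && !(t[1] == s[1] && t[2] == s[2])
    }, logical(1)))
  }, cov)
  width_ok <- Filter(function(s) s[2] - s[1] + 1L <= q$window, minimal)
  if (!length(width_ok)) return(empty)
  neg <- which(norm %in% q$negation_terms)
  negated <- vapply(width_ok, function(s) {
    length(neg) > 0 && any(pmax(s[2], neg) - pmin(s[1], neg) + 1L <= q$window)
  }, logical(1))
  if (identical(q$negation_scope, "document") && any(negated)) return(empty)
  keep <- width_ok[!negated]
  if (!length(keep)) return(empty)
  m <- do.call(rbind, keep)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  data.frame(start = m[, 1], end = m[, 2])
}

naive_phrase_hit <- function(norm, phrase) {
  k <- length(phrase)
  n <- length(norm)
  if (n < k) return(FALSE)
  for (i in seq_len(n - k + 1L)) {
    if (all(norm[i:(i + k - 1L)] == phrase)) return(TRUE)
  }
  FALSE
}

naive_doc_hit <- function(norm, q) {
  if (inherits(q, "phrase_query")) return(naive_phrase_hit(norm, q$phrase))
  if (inherits(q, "span_query")) return(nrow(oracle_match_span(norm, q)) > 0L)
  if (inherits(q, "bool_query")) {
    hits <- vapply(q$children, naive_doc_hit, logical(1), norm = norm)
    return(if (q$operator == "OR") any(hits) else all(hits))
  }
  stop("unknown query type in oracle")
}

# Index-free evaluator: scans every document directly.
naive_execute <- function(corpus, q) {
  docs <- corpus$documents
  hit <- vapply(seq_len(nrow(docs)), function(i) {
    norm <- tokenize(paste(docs$title[i], docs$text[i],
                           sep = "\n"))$normalized
    naive_doc_hit(norm, q)
  }, logical(1))
  sort(docs$doc_id[hit])
}

clinical_vocab <- c("chest", "ct", "scan", "nodule", "recurrence", "stable",
                    "mass", "worrisome", "no", "not", "lung", "benign",
                    "opacity", "pet", "concerning", "metastatic", "prior",
                    "imaging", "left", "right")

random_corpus <- function(n_docs, vocab = clinical_vocab,
                          min_len = 3L, max_len = 30L) {
  texts <- vapply(seq_len(n_docs), function(i) {
    paste(sample(vocab, sample(min_len:max_len, 1L), replace = TRUE),
          collapse = " ")
  }, "")
  report_corpus(data.frame(
    doc_id = sprintf("d%03d", seq_len(n_docs)),
    patient_id = sprintf("p%02d", sample.int(max(1L, n_docs %/% 3L),
                                             n_docs, replace = TRUE)),
    report_date = "2012-01-01",
    title = vapply(seq_len(n_docs), function(i)
      paste(sample(vocab, 3L), collapse = " "), ""),
    text = texts, stringsAsFactors = FALSE))
}

random_span_query <- function(vocab = clinical_vocab) {
  n_groups <- sample(2:3, 1L)
  span_query(lapply(seq_len(n_groups), function(i)
               sample(vocab, sample(1:3, 1L))),
             window = sample(n_groups:10, 1L),
             negation_terms = sample(vocab, sample(0:2, 1L)),
             ordered = stats::runif(1) < 0.3)
}

random_query <- function(vocab = clinical_vocab, depth = 3L) {
  if (depth <= 0L || stats::runif(1) < 0.45) {
    if (stats::runif(1) < 0.55) {
      return(phrase_query(sample(vocab, sample(1:3, 1L), replace = TRUE)))
    }
    return(random_span_query(vocab))
  }
  kids <- lapply(seq_len(sample(2:3, 1L)), function(i)
    random_query(vocab, depth - 1L))
  bool_query(sample(c("AND", "OR"), 1L), kids)
}

spans_equal <- function(a, b) {
  isTRUE(all.equal(as.integer(a$start), as.integer(b$start))) &&
    isTRUE(all.equal(as.integer(a$end), as.integer(b$end)))
}
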