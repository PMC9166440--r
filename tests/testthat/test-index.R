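two_doc_corpus <- function() {
  report_corpus(data.frame(
    doc_id = c("a", "b"),
    patient_id = c("p1", "p2"),
    report_date = "2010-01-01",
    title = c("CT CHEST", "CHEST X RAY"),
    text = c("Stable chest nodule.", "Clear chest."),
    stringsAsFactors = FALSE))
}

test_that("postings cover every token exactly once", {
  corp <- two_doc_corpus()
  idx <- build_index(corp)
  expect_setequal(names(term_postings(idx, "chest")), c("a", "b"))
  total <- sum(vapply(ls(idx$postings), function(t)
    sum(lengths(term_postings(idx, t))), numeric(1)))
  expect_equal(total, idx$n_tokens)
  # 1-doc corpus with 7 tokens conserves its postings count
  corp1 <- report_corpus(data.frame(
    doc_id = "x", patient_id = "p", report_date = "2010-01-01",
    title = "BONE SCAN", text = "New lesion in left femur.",
    stringsAsFactors = FALSE))
  idx1 <- build_index(corp1)
  expect_equal(idx1$n_tokens, 7L)
})

test_that("index postings agree with a naive full scan on a random corpus", {
  set.seed(12)
  corp <- random_corpus(50)
  idx <- build_index(corp)
  docs <- corp$documents
  streams <- lapply(seq_len(nrow(docs)), function(i)
    tokenize(paste(docs$title[i], docs$text[i], sep = "\n"))$normalized)
  names(streams) <- docs$doc_id
  all_terms <- sort(unique(unlist(streams)))
  expect_setequal(ls(idx$postings), all_terms)
  for (term in all_terms) {
    expected <- Filter(length, lapply(streams, function(s) which(s == term)))
    got <- term_postings(idx, term)
    expect_equal(got[order(names(got))], expected[order(names(expected))],
                 info = term)
  }
})

test_that("boolean execution is set algebra over children", {
  corp <- two_doc_corpus()
  idx <- build_index(corp)
  qa <- phrase_query("nodule")    # only doc a
  qb <- phrase_query("x ray")     # only doc b
  expect_equal(execute_query(idx, or_query(qa, qb))$doc_ids, c("a", "b"))
  expect_equal(execute_query(idx, and_query(qa, qb))$doc_ids, character())
  # AND of a matching and non-matching child on the same doc drops it
  expect_equal(execute_query(idx, and_query(qa, phrase_query("missing")))$doc_ids,
               character())
  expect_equal(execute_query(idx, and_query(qa, phrase_query("stable")))$doc_ids,
               "a")
})

test_that("indexed execution equals an index-free per-document scan", {
  set.seed(2024)
  for (rep in 1:40) {
    corp <- random_corpus(sample(5:60, 1L))
    idx <- build_index(corp)
    for (k in 1:3) {
      q <- random_query(depth = 3L)
      expect_equal(execute_query(idx, q)$doc_ids, naive_execute(corp, q),
                   info = paste("rep", rep, format_query(q)))
    }
  }
})

test_that("OR grows monotonically and AND shrinks monotonically", {
  set.seed(404)
  corp <- random_corpus(40)
  idx <- build_index(corp)
  for (i in 1:25) {
    kids <- lapply(1:2, function(j) random_query(depth = 1L))
    extra <- random_query(depth = 1L)
    or_base <- execute_query(idx, bool_query("OR", kids))$doc_ids
    or_more <- execute_query(idx, bool_query("OR", c(kids, list(extra))))$doc_ids
    expect_true(all(or_base %in% or_more))
    and_base <- execute_query(idx, bool_query("AND", kids))$doc_ids
    and_more <- execute_query(idx, bool_query("AND", c(kids, list(extra))))$doc_ids
    expect_true(all(and_more %in% and_base))
  }
})

test_that("execution is deterministic", {
  set.seed(7)
  corp <- random_corpus(30)
  q <- random_query(depth = 2L)
  idx <- build_index(corp)
  r1 <- execute_query(idx, q)
  r2 <- execute_query(build_index(corp), q)
  expect_identical(r1$doc_ids, r2$doc_ids)
  expect_identical(r1$spans, r2$spans)
})

test_that("snippets cover matches with context and valid highlights", {
  doc <- list(doc_id = "d1", title = "CT CHEST",
              text = "Indication: surveillance. Findings: new nodule worrisome for recurrence in the left lower lobe.")
  full <- paste(doc$title, doc$text, sep = "\n")
  ts <- tokenize(full)
  q <- span_query(list("worrisome", "recurrence"), window = 10)
  spans <- match_span(ts, q)
  snip <- make_snippet(doc, spans, context_tokens = 5)
  expect_s3_class(snip, "snippet")
  # every highlight lies inside the document text
  expect_true(all(snip$highlight_spans$char_start >= 1))
  expect_true(all(snip$highlight_spans$char_end <= nchar(full)))
  # window covers span +- context tokens
  lo <- max(1L, spans$start - 5L); hi <- min(nrow(ts), spans$end + 5L)
  expect_equal(snip$window_text,
               substring(full, ts$char_start[lo], ts$char_end[hi]))
  # highlighting specific terms points at those term occurrences
  snip2 <- make_snippet(doc, spans, terms = c("worrisome", "recurrence"))
  words <- substring(full, snip2$highlight_spans$char_start,
                     snip2$highlight_spans$char_end)
  expect_setequal(tolower(words), c("worrisome", "recurrence"))
})

test_that("snippets truncate at document boundaries and merge windows", {
  doc <- list(doc_id = "d2", title = "CHEST X RAY", text = "clear lungs")
  full <- paste(doc$title, doc$text, sep = "\n")
  ts <- tokenize(full)
  snip <- make_snippet(doc, data.frame(start = 1L, end = 1L),
                       context_tokens = 3)
  expect_equal(snip$windows$start, 1L)
  # multi-match: overlapping context windows merge; re-scan check
  doc3 <- list(doc_id = "d3", title = "T",
               text = paste(rep("x", 30), collapse = " "))
  spans3 <- data.frame(start = c(2L, 5L, 25L), end = c(2L, 5L, 25L))
  snip3 <- make_snippet(doc3, spans3, context_tokens = 3)
  expect_equal(nrow(snip3$windows), 2L)  # first two merge, third separate
  expect_error(make_snippet(doc, data.frame(start = 1L, end = 99L)),
               "outside document")
})
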