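make_docs <- function(n = 3L) {
  data.frame(doc_id = sprintf("r%d", seq_len(n)),
             patient_id = "p1", report_date = "2013-05-02",
             title = "CT CHEST", text = "Stable examination.",
             stringsAsFactors = FALSE)
}

test_that("jsonl corpus round-trips and counts non-blank lines", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  docs <- make_docs(3)
  writeLines(c(
    vapply(seq_len(3), function(i)
      as.character(jsonlite::toJSON(as.list(docs[i, ]), auto_unbox = TRUE)),
      ""),
    ""), path)  # trailing blank line must be ignored
  corp <- read_corpus(path)
  expect_s3_class(corp, "report_corpus")
  expect_equal(n_documents(corp), 3L)
  expect_equal(corp$documents$doc_id, docs$doc_id)
})

test_that("empty corpus file yields an empty corpus without error", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(), path)
  expect_equal(n_documents(read_corpus(path)), 0L)
})

test_that("malformed and duplicate records fail with location info", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"doc_id":"r1","patient_id":"p","report_date":"2013-05-02","title":"t","text":"x"}',
               '{"doc_id":"r2","patient_id":"p"}'), path)
  expect_error(read_corpus(path), "line 2.*missing field.*report_date")

  writeLines('{"doc_id":"r1","patient_id":"p"', path)
  expect_error(read_corpus(path), "line 1.*malformed")

  docs <- make_docs(2)
  docs$doc_id <- c("r1", "r1")
  expect_error(report_corpus(docs), "duplicate doc_id")
})

test_that("dates are normalized to ISO-8601 on ingest", {
  docs <- make_docs(1)
  docs$report_date <- "05/02/2013"
  expect_equal(report_corpus(docs)$documents$report_date, "2013-05-02")
  docs$report_date <- "garbage"
  expect_error(report_corpus(docs), "unparseable")
})

test_that("annotation export round-trips in both formats", {
  docs <- make_docs(5)
  ann <- data.frame(doc_id = docs$doc_id, source = "gold",
                    image_type = c("ct_chest", "chest_xray", "pet",
                                   "null", "mri_brain"),
                    indication = c("surveillance", "symptomatic", "other",
                                   "null", "unknown"),
                    findings = c("suspicious", "benign", "recurrence",
                                 "null", "nonspecific"),
                    stringsAsFactors = FALSE)
  corp <- report_corpus(docs, ann)
  for (ext in c(".jsonl", ".csv")) {
    path <- withr::local_tempfile(fileext = ext)
    n <- write_annotations(corp, path)
    expect_equal(n, 5L)
    back <- read_annotations(path)
    expect_equal(back, annotations(corp))
  }
})

test_that("empty annotation export writes a header-only csv and returns 0", {
  corp <- report_corpus(make_docs(2))
  path <- withr::local_tempfile(fileext = ".csv")
  expect_equal(write_annotations(corp, path), 0L)
  expect_equal(nrow(read_annotations(path)), 0L)
})

test_that("null labels survive the round trip as literal strings", {
  docs <- make_docs(1)
  ann <- data.frame(doc_id = "r1", source = "gold", image_type = "null",
                    indication = "null", findings = "null",
                    stringsAsFactors = FALSE)
  corp <- report_corpus(docs, ann)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_annotations(corp, path)
  expect_equal(read_annotations(path)$image_type, "null")
})

test_that("out-of-vocabulary labels are rejected at read time", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(doc_id = "r1", source = "gold",
                              image_type = "ultrasound",
                              indication = "surveillance",
                              findings = "benign"),
                   path, row.names = FALSE)
  expect_error(read_annotations(path), "out-of-vocabulary")
})

test_that("annotations must resolve to documents, one per doc and source", {
  docs <- make_docs(1)
  ann <- data.frame(doc_id = "missing", source = "gold",
                    image_type = "ct_chest", indication = "other",
                    findings = "benign", stringsAsFactors = FALSE)
  expect_error(report_corpus(docs, ann), "not present in corpus")
  ann2 <- data.frame(doc_id = c("r1", "r1"), source = "gold",
                     image_type = "ct_chest", indication = "other",
                     findings = "benign", stringsAsFactors = FALSE)
  expect_error(report_corpus(docs, ann2), "more than one annotation")
})
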