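#' @title Label vocabularies
#' @description Closed label vocabularies for the three annotation axes used
#'   in lung-cancer surveillance chart abstraction. `"null"` marks a report
#'   irrelevant to surveillance (e.g. an extremity radiograph); it is a real
#'   label, distinct from "unannotated".
#' @param axis one of `"image_type"`, `"indication"`, `"findings"`.
#' @return character vector of allowed labels for that axis.
#' @export
#' @examples
#' axis_labels("indication")
axis_labels <- function(axis = c("image_type", "indication", "findings")) {
  axis <- match.arg(axis)
  switch(axis,
    image_type = c("bone_scan", "chest_xray", "ct_abdomen_pelvis",
                   "ct_chest", "ct_chest_abdomen_pelvis", "ct_head",
                   "mri_body", "mri_brain", "pet", "null"),
    indication = c("surveillance", "symptomatic", "followup_abnormal_chest",
                   "followup_abnormal_other", "other", "unknown", "null"),
    findings   = c("suspicious", "recurrence", "benign", "nonspecific",
                   "second_primary_lung", "second_primary_other",
                   "other_unrelated", "null"))
}

ANNOTATION_AXES <- c("image_type", "indication", "findings")
DOCUMENT_FIELDS <- c("doc_id", "patient_id", "report_date", "title", "text")
ANNOTATION_FIELDS <- c("doc_id", "source", ANNOTATION_AXES)

# Normalize assorted date dialects to ISO-8601; error on unparseable input.
normalize_dates <- function(x, context = "report_date") {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  fmts <- c("%Y-%m-%d", "%Y/%m/%d", "%m/%d/%Y", "%m-%d-%Y", "%d %b %Y",
            "%b %d, %Y")
  pending <- !is.na(x) & nzchar(x)
  for (f in fmts) {
    if (!any(pending)) break
    d <- as.Date(x[pending], format = f)
    # strict: a format only counts if it reproduces the input exactly,
    # so "05/02/2013" cannot be half-parsed as year 5
    hit <- !is.na(d) & format(d, f) == x[pending]
    out[which(pending)[hit]] <- format(d[hit], "%Y-%m-%d")
    pending[pending] <- !hit
  }
  if (any(pending)) {
    stop(sprintf("unparseable %s value(s): %s", context,
                 paste(unique(x[pending]), collapse = ", ")), call. = FALSE)
  }
  out
}

validate_annotation_labels <- function(ann, where = "annotations") {
  for (axis in ANNOTATION_AXES) {
    bad <- !is.na(ann[[axis]]) & !(ann[[axis]] %in% axis_labels(axis))
    if (any(bad)) {
      stop(sprintf("%s: out-of-vocabulary %s label(s): %s", where, axis,
                   paste(unique(ann[[axis]][bad]), collapse = ", ")),
           call. = FALSE)
    }
  }
  bad_src <- !(ann$source %in% c("gold", "predicted"))
  if (any(bad_src)) {
    stop(sprintf("%s: source must be 'gold' or 'predicted', got: %s", where,
                 paste(unique(ann$source[bad_src]), collapse = ", ")),
         call. = FALSE)
  }
  invisible(ann)
}

empty_annotations <- function() {
  data.frame(doc_id = character(), source = character(),
             image_type = character(), indication = character(),
             findings = character(), stringsAsFactors = FALSE)
}

#' Construct a report corpus
#'
#' A corpus bundles an ordered collection of radiology report documents
#' (opaque patient identifier, report date, document title, free text) with
#' report-level annotations on the three abstraction axes (image type,
#' indication, findings), keyed by `(doc_id, source)` where source is
#' `"gold"` (manual abstraction) or `"predicted"` (rule output).
#'
#' @param documents data.frame with columns `doc_id`, `patient_id`,
#'   `report_date`, `title`, `text`. `doc_id` must be unique; dates are
#'   normalized to ISO-8601; `text` may be empty but not `NA`.
#' @param annotations optional data.frame with columns `doc_id`, `source`,
#'   `image_type`, `indication`, `findings`. Every `doc_id` must resolve to
#'   a document; labels are checked against the closed vocabularies.
#' @return an object of class `report_corpus`.
#' @seealso [read_corpus()], [generate_corpus()]
#' @export
report_corpus <- function(documents, annotations = NULL) {
  stopifnot(is.data.frame(documents))
  missing_cols <- setdiff(DOCUMENT_FIELDS, names(documents))
  if (length(missing_cols)) {
    stop("documents missing field(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  documents <- documents[, DOCUMENT_FIELDS, drop = FALSE]
  for (f in DOCUMENT_FIELDS) documents[[f]] <- as.character(documents[[f]])
  dup <- duplicated(documents$doc_id)
  if (any(dup)) {
    stop("duplicate doc_id: ", paste(unique(documents$doc_id[dup]),
                                     collapse = ", "), call. = FALSE)
  }
  if (anyNA(documents$text)) {
    stop("document text may be empty but never absent (NA)", call. = FALSE)
  }
  documents$report_date <- normalize_dates(documents$report_date)
  if (is.null(annotations)) annotations <- empty_annotations()
  missing_cols <- setdiff(ANNOTATION_FIELDS, names(annotations))
  if (length(missing_cols)) {
    stop("annotations missing field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  annotations <- annotations[, ANNOTATION_FIELDS, drop = FALSE]
  for (f in ANNOTATION_FIELDS) annotations[[f]] <- as.character(annotations[[f]])
  orphan <- setdiff(annotations$doc_id, documents$doc_id)
  if (length(orphan)) {
    stop("annotation doc_id(s) not present in corpus: ",
         paste(utils::head(orphan, 5L), collapse = ", "), call. = FALSE)
  }
  key <- paste(annotations$doc_id, annotations$source)
  if (anyDuplicated(key)) {
    stop("more than one annotation per (doc_id, source): ",
         paste(utils::head(unique(key[duplicated(key)]), 5L), collapse = "; "),
         call. = FALSE)
  }
  validate_annotation_labels(annotations)
  rownames(documents) <- NULL
  rownames(annotations) <- NULL
  structure(list(documents = documents, annotations = annotations),
            class = "report_corpus")
}

#' @export
print.report_corpus <- function(x, ...) {
  cat(sprintf("<report_corpus> %d reports, %d patients, %d annotations\n",
              nrow(x$documents), length(unique(x$documents$patient_id)),
              nrow(x$annotations)))
  if (nrow(x$annotations)) {
    cat("  sources:", paste(sort(unique(x$annotations$source)),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of documents in a corpus
#' @param corpus a `report_corpus`.
#' @return integer count.
#' @export
n_documents <- function(corpus) nrow(corpus$documents)

#' Retrieve annotations from a corpus
#' @param corpus a `report_corpus`.
#' @param source `"gold"`, `"predicted"`, or `NULL` for all.
#' @return data.frame of annotation records.
#' @export
annotations <- function(corpus, source = NULL) {
  ann <- corpus$annotations
  if (!is.null(source)) ann <- ann[ann$source %in% source, , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Replace or add annotations for one source
#'
#' Drops any existing annotations with the same source before appending, so
#' re-running a classifier overwrites its previous predictions.
#'
#' @param corpus a `report_corpus`.
#' @param ann data.frame with the annotation fields.
#' @return the updated `report_corpus`.
#' @export
set_annotations <- function(corpus, ann) {
  stopifnot(inherits(corpus, "report_corpus"))
  keep <- corpus$annotations[!(corpus$annotations$source %in% ann$source), ,
                             drop = FALSE]
  report_corpus(corpus$documents, rbind(keep, ann[, ANNOTATION_FIELDS]))
}

# Title and body are searched together: rules scan the entire scope of the
# document, mirroring how the search tool indexes full reports.
full_text <- function(title, text) {
  paste(title, text, sep = "\n")
}

#' Read a report corpus from disk
#'
#' @param path file path. JSONL: one object per line with keys `doc_id`,
#'   `patient_id`, `report_date`, `title`, `text`; blank lines are ignored.
#'   CSV: UTF-8, comma-delimited, quoted text field, same columns.
#' @param format `"jsonl"` or `"csv"`; default guessed from the extension.
#' @return a `report_corpus` (without annotations; see [read_annotations()]).
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- resolve_format(match.arg(format), path)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "jsonl") {
    docs <- read_jsonl_records(path, DOCUMENT_FIELDS)
  } else {
    docs <- utils::read.csv(path, colClasses = "character",
                            stringsAsFactors = FALSE)
    missing_cols <- setdiff(DOCUMENT_FIELDS, names(docs))
    if (length(missing_cols)) {
      stop(sprintf("%s: missing column(s): %s", path,
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
  }
  if (nrow(docs) == 0L) {
    docs <- data.frame(doc_id = character(), patient_id = character(),
                       report_date = character(), title = character(),
                       text = character(), stringsAsFactors = FALSE)
  }
  report_corpus(docs)
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
}

# Line-by-line JSONL reader so malformed records are reported with their
# line number and the missing field named.
read_jsonl_records <- function(path, required) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(nzchar(trimws(lines)))
  recs <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    rec <- tryCatch(jsonlite::fromJSON(lines[ln]),
                    error = function(e) {
                      stop(sprintf("%s line %d: malformed JSON (%s)", path, ln,
                                   conditionMessage(e)), call. = FALSE)
                    })
    miss <- setdiff(required, names(rec))
    if (length(miss)) {
      stop(sprintf("%s line %d: missing field(s): %s", path, ln,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    recs[[i]] <- lapply(rec[required], function(v) {
      if (is.null(v)) NA_character_ else as.character(v)
    })
  }
  if (!length(recs)) {
    out <- as.data.frame(stats::setNames(rep(list(character()), length(required)),
                                         required),
                         stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, lapply(recs, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out
}

#' Write corpus documents to disk
#' @param corpus a `report_corpus`.
#' @param path output file path.
#' @param format `"jsonl"` or `"csv"` (default from extension).
#' @return (invisibly) the number of records written.
#' @export
write_corpus <- function(corpus, path, format = c("auto", "jsonl", "csv")) {
  format <- resolve_format(match.arg(format), path)
  write_records(corpus$documents, path, format)
}

#' Write annotations to disk
#'
#' One record per `(doc_id, source)` pair, with the three axis labels as
#' columns. `"null"` labels are written as the literal string `"null"`, never
#' as an absent field, so "irrelevant report" stays distinct from
#' "unannotated". A round trip through [read_annotations()] reproduces the
#' annotation table exactly.
#'
#' @param corpus a `report_corpus`.
#' @param path output file path.
#' @param format `"jsonl"` or `"csv"` (default from extension).
#' @param source restrict export to one source (default: all).
#' @return (invisibly) the number of annotation records written.
#' @export
write_annotations <- function(corpus, path,
                              format = c("auto", "jsonl", "csv"),
                              source = NULL) {
  format <- resolve_format(match.arg(format), path)
  write_records(annotations(corpus, source), path, format)
}

write_records <- function(df, path, format) {
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    if (nrow(df)) {
      for (i in seq_len(nrow(df))) {
        writeLines(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                    auto_unbox = TRUE), con)
      }
    }
  }
  invisible(nrow(df))
}

#' Read annotations from disk
#'
#' Labels are validated against the closed per-axis vocabularies; any
#' out-of-vocabulary label is rejected at read time.
#'
#' @param path file path (JSONL or CSV with columns `doc_id`, `source`,
#'   `image_type`, `indication`, `findings`).
#' @param format `"jsonl"` or `"csv"` (default from extension).
#' @return data.frame of annotation records.
#' @export
read_annotations <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- resolve_format(match.arg(format), path)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "jsonl") {
    ann <- read_jsonl_records(path, ANNOTATION_FIELDS)
  } else {
    ann <- utils::read.csv(path, colClasses = "character",
                           stringsAsFactors = FALSE)
    missing_cols <- setdiff(ANNOTATION_FIELDS, names(ann))
    if (length(missing_cols)) {
      stop(sprintf("%s: missing column(s): %s", path,
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
  }
  if (nrow(ann) == 0L) return(empty_annotations())
  ann <- ann[, ANNOTATION_FIELDS, drop = FALSE]
  validate_annotation_labels(ann, where = path)
  ann
}
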