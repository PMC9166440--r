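#' Flag reports relevant to surveillance abstraction
#'
#' Applies the OR-union of every image-type rule: a report is a "relevant
#' study" iff at least one image-type query retrieves it. This is the
#' pre-processing filter of the semi-automated workflow — everything it
#' drops is never shown to the abstractor. Removing any per-type rule can
#' only shrink the returned set.
#'
#' @param corpus a `report_corpus`.
#' @param rules an image-type `rule_set` (default: shipped rules).
#' @param index optional pre-built `report_index`.
#' @return sorted character vector of relevant `doc_id`s.
#' @export
classify_relevance <- function(corpus, rules = default_rules("image_type"),
                               index = NULL) {
  stopifnot(inherits(rules, "rule_set"))
  if (rules$axis != "image_type") {
    stop("classify_relevance needs image_type rules", call. = FALSE)
  }
  if (n_documents(corpus) == 0L) return(character())
  if (is.null(index)) index <- build_index(corpus)
  if (!length(rules$rules)) return(character())
  union_q <- bool_query("OR", unname(rules$rules))
  execute_query(index, union_q)$doc_ids
}

#' Classify every report on one annotation axis
#'
#' Per document: the label whose query retrieves it; when several rules
#' fire, the first-listed label wins and the conflict is recorded. When no
#' rule fires the rule set's default label is applied. Application is
#' deterministic and order-stable.
#'
#' @param corpus a `report_corpus`.
#' @param rules a `rule_set` for the axis being classified.
#' @param index optional pre-built `report_index`.
#' @return data.frame with columns `doc_id`, `label`, plus a `multi_fire`
#'   attribute: data.frame of documents matched by more than one label and
#'   the labels that fired (comma-separated, rule order).
#' @export
classify_axis <- function(corpus, rules, index = NULL) {
  stopifnot(inherits(corpus, "report_corpus"), inherits(rules, "rule_set"))
  ids <- corpus$documents$doc_id
  out <- data.frame(doc_id = ids, label = rep(rules$default_label,
                                              length(ids)),
                    stringsAsFactors = FALSE)
  if (!length(ids) || !length(rules$rules)) {
    attr(out, "multi_fire") <- data.frame(doc_id = character(),
                                          labels = character(),
                                          stringsAsFactors = FALSE)
    return(out)
  }
  if (is.null(index)) index <- build_index(corpus)
  fired <- stats::setNames(vector("list", length(rules$rules)),
                           names(rules$rules))
  for (lbl in names(rules$rules)) {
    fired[[lbl]] <- execute_query(index, rules$rules[[lbl]])$doc_ids
  }
  assigned <- rep(NA_character_, length(ids))
  names(assigned) <- ids
  n_fired <- stats::setNames(integer(length(ids)), ids)
  fired_labels <- stats::setNames(vector("list", length(ids)), ids)
  for (lbl in names(fired)) {
    hit <- fired[[lbl]]
    first <- hit[is.na(assigned[hit])]
    assigned[first] <- lbl
    n_fired[hit] <- n_fired[hit] + 1L
    for (d in hit) fired_labels[[d]] <- c(fired_labels[[d]], lbl)
  }
  out$label <- ifelse(is.na(assigned), rules$default_label, assigned)
  multi <- names(n_fired)[n_fired > 1L]
  attr(out, "multi_fire") <- data.frame(
    doc_id = multi,
    labels = vapply(fired_labels[multi], paste, "", collapse = ","),
    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Predict annotations on all three axes
#'
#' Runs [classify_axis()] with each rule set and assembles a predicted
#' annotation table. Reports not flagged by the relevance filter keep the
#' image-type default label (`"null"`).
#'
#' @param corpus a `report_corpus`.
#' @param image_type_rules,indication_rules,findings_rules rule sets
#'   (defaults: shipped rules).
#' @param index optional pre-built `report_index`.
#' @return annotation data.frame with `source = "predicted"`.
#' @export
predict_annotations <- function(corpus,
                                image_type_rules = default_rules("image_type"),
                                indication_rules = default_rules("indication"),
                                findings_rules = default_rules("findings"),
                                index = NULL) {
  if (is.null(index)) index <- build_index(corpus)
  img <- classify_axis(corpus, image_type_rules, index = index)
  ind <- classify_axis(corpus, indication_rules, index = index)
  fnd <- classify_axis(corpus, findings_rules, index = index)
  data.frame(doc_id = img$doc_id, source = "predicted",
             image_type = img$label,
             indication = ind$label[match(img$doc_id, ind$doc_id)],
             findings = fnd$label[match(img$doc_id, fnd$doc_id)],
             stringsAsFactors = FALSE)
}
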