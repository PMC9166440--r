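#' Build a 2x2 confusion matrix from gold and predicted labels
#'
#' @param gold,predicted either named character vectors (names are doc ids)
#'   or data.frames with columns `doc_id` and a label column (`label`, or
#'   the axis name). Both must cover exactly the same doc ids.
#' @param positive label (or set of labels) treated as the positive class.
#' @return an object of class `confusion_matrix` with integer fields `tp`,
#'   `fp`, `fn`, `tn`; the four cells always sum to the number of evaluated
#'   reports.
#' @export
#' @examples
#' confusion(c(a = "x", b = "x", c = "y", d = "y"),
#'           c(a = "x", b = "y", c = "x", d = "y"), positive = "x")
confusion <- function(gold, predicted, positive) {
  g <- as_label_vector(gold, "gold")
  p <- as_label_vector(predicted, "predicted")
  only_g <- setdiff(names(g), names(p))
  only_p <- setdiff(names(p), names(g))
  if (length(only_g) || length(only_p)) {
    stop(sprintf(
      "gold and predicted cover different doc_ids (only gold: %s; only predicted: %s)",
      paste(utils::head(only_g, 5L), collapse = ","),
      paste(utils::head(only_p, 5L), collapse = ",")), call. = FALSE)
  }
  p <- p[names(g)]
  gp <- g %in% positive
  pp <- p %in% positive
  confusion_counts(tp = sum(gp & pp), fp = sum(!gp & pp),
                   fn = sum(gp & !pp), tn = sum(!gp & !pp))
}

as_label_vector <- function(x, what) {
  if (is.data.frame(x)) {
    if (!"doc_id" %in% names(x)) {
      stop(what, " data.frame needs a doc_id column", call. = FALSE)
    }
    lab_col <- setdiff(names(x), c("doc_id", "source"))
    if ("label" %in% lab_col) lab_col <- "label"
    if (length(lab_col) != 1L) {
      stop(what, " data.frame needs exactly one label column", call. = FALSE)
    }
    return(stats::setNames(as.character(x[[lab_col]]), x$doc_id))
  }
  if (is.null(names(x))) {
    stop(what, " label vector must be named by doc_id", call. = FALSE)
  }
  stats::setNames(as.character(x), names(x))
}

#' Confusion matrix from raw counts
#' @param tp,fp,fn,tn non-negative integer report counts.
#' @return a `confusion_matrix`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("confusion cells must be non-negative integers", call. = FALSE)
  }
  cells <- stats::setNames(as.integer(round(cells)), names(cells))
  structure(as.list(cells), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(gold = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  print(t(m))
  invisible(x)
}

# Clopper-Pearson exact interval via the beta quantile identity.
ci_clopper_pearson <- function(x, n, conf_level) {
  a <- 1 - conf_level
  lower <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lower, upper)
}

# Wilson score interval (no continuity correction).
ci_wilson <- function(x, n, conf_level) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  phat <- x / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

proportion_with_ci <- function(x, n, method, conf_level) {
  if (n == 0) {
    return(list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                undefined = TRUE))
  }
  ci <- switch(method,
               clopper_pearson = ci_clopper_pearson(x, n, conf_level),
               wilson = ci_wilson(x, n, conf_level))
  list(estimate = x / n, ci = ci, undefined = FALSE)
}

#' Performance metrics from a confusion matrix
#'
#' Sensitivity (recall) `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive
#' predictive value (precision) `tp/(tp+fp)`, and
#' `F1 = 2 * (sensitivity * PPV) / (sensitivity + PPV)` computed from the
#' unrounded proportions. A zero denominator yields an explicit undefined
#' marker (`NA` plus the metric name in `$undefined`), never a silent 0 or
#' 1. Confidence intervals are Clopper-Pearson exact by default (the
#' conventional, conservative choice for test-performance reporting) or
#' Wilson score.
#'
#' @param cm a `confusion_matrix`.
#' @param ci_method `"clopper_pearson"` (default) or `"wilson"`.
#' @param conf_level confidence level (default 0.95).
#' @return an object of class `query_metrics`: raw proportions, CI bounds,
#'   `f1`, `n_evaluated`, and `undefined` (character vector of metrics with
#'   empty denominators).
#' @export
#' @examples
#' metrics(confusion_counts(tp = 2548, fp = 133, fn = 463, tn = 47))
metrics <- function(cm, ci_method = c("clopper_pearson", "wilson"),
                    conf_level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ci_method <- match.arg(ci_method)
  sens <- proportion_with_ci(cm$tp, cm$tp + cm$fn, ci_method, conf_level)
  spec <- proportion_with_ci(cm$tn, cm$tn + cm$fp, ci_method, conf_level)
  ppv <- proportion_with_ci(cm$tp, cm$tp + cm$fp, ci_method, conf_level)
  undefined <- c("sensitivity", "specificity", "ppv")[
    c(sens$undefined, spec$undefined, ppv$undefined)]
  f1 <- if (sens$undefined || ppv$undefined ||
            (sens$estimate + ppv$estimate) == 0) {
    undefined <- c(undefined, "f1")
    NA_real_
  } else {
    2 * (sens$estimate * ppv$estimate) / (sens$estimate + ppv$estimate)
  }
  structure(list(
    confusion = cm,
    sensitivity = sens$estimate, sensitivity_ci = sens$ci,
    specificity = spec$estimate, specificity_ci = spec$ci,
    ppv = ppv$estimate, ppv_ci = ppv$ci,
    f1 = f1,
    n_evaluated = cm$tp + cm$fp + cm$fn + cm$tn,
    ci_method = ci_method, conf_level = conf_level,
    undefined = undefined),
    class = "query_metrics")
}

# Display rounding used in performance tables: whole percents for the three
# proportions, two decimals for F1. Raw values stay in the object.
round_pct <- function(x) ifelse(is.na(x), NA_real_, round(100 * x))

#' Rounded display values for a metrics object
#' @param m a `query_metrics`.
#' @return named list: `sensitivity_pct`, `specificity_pct`, `ppv_pct`
#'   (whole percents, with CI bounds), `f1` (2 decimals).
#' @export
metric_display <- function(m) {
  stopifnot(inherits(m, "query_metrics"))
  list(sensitivity_pct = round_pct(m$sensitivity),
       sensitivity_ci_pct = round_pct(m$sensitivity_ci),
       specificity_pct = round_pct(m$specificity),
       specificity_ci_pct = round_pct(m$specificity_ci),
       ppv_pct = round_pct(m$ppv),
       ppv_ci_pct = round_pct(m$ppv_ci),
       f1 = if (is.na(m$f1)) NA_real_ else round(m$f1, 2))
}

#' @export
print.query_metrics <- function(x, ...) {
  d <- metric_display(x)
  fmt <- function(v, ci) {
    if (is.na(v)) return("undefined")
    sprintf("%d%% (%d-%d%%)", v, ci[1], ci[2])
  }
  cat(sprintf("<query_metrics> n=%d (%s CI)\n", x$n_evaluated, x$ci_method))
  cat("  sensitivity:", fmt(d$sensitivity_pct, d$sensitivity_ci_pct), "\n")
  cat("  specificity:", fmt(d$specificity_pct, d$specificity_ci_pct), "\n")
  cat("  PPV:        ", fmt(d$ppv_pct, d$ppv_ci_pct), "\n")
  cat("  F1:         ", ifelse(is.na(d$f1), "undefined",
                               sprintf("%.2f", d$f1)), "\n")
  invisible(x)
}

#' One-vs-rest metrics per label
#'
#' For each label, computes the 2x2 confusion of "gold == label" against
#' "predicted == label" and the derived metrics — the per-image-type
#' breakdown of a type classifier's performance.
#'
#' @param gold,predicted as in [confusion()].
#' @param labels labels to evaluate (default: all labels present in gold
#'   except `"null"`).
#' @param ci_method,conf_level passed to [metrics()].
#' @return data.frame with one row per label (tp, fp, fn, tn, rounded
#'   sensitivity/specificity/PPV percents, F1); full `query_metrics`
#'   objects in the `metrics` attribute.
#' @export
per_type_metrics <- function(gold, predicted, labels = NULL,
                             ci_method = "clopper_pearson",
                             conf_level = 0.95) {
  g <- as_label_vector(gold, "gold")
  if (is.null(labels)) labels <- setdiff(sort(unique(g)), "null")
  res <- lapply(labels, function(lbl) {
    metrics(confusion(gold, predicted, positive = lbl),
            ci_method = ci_method, conf_level = conf_level)
  })
  names(res) <- labels
  tab <- do.call(rbind, lapply(labels, function(lbl) {
    m <- res[[lbl]]
    d <- metric_display(m)
    data.frame(label = lbl, tp = m$confusion$tp, fp = m$confusion$fp,
               fn = m$confusion$fn, tn = m$confusion$tn,
               sensitivity_pct = d$sensitivity_pct,
               specificity_pct = d$specificity_pct,
               ppv_pct = d$ppv_pct, f1 = d$f1,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  attr(tab, "metrics") <- res
  tab
}

#' Write a metrics report
#'
#' One row per query/label with the confusion cells, rounded metrics and
#' confidence intervals, as CSV.
#'
#' @param results named list of `query_metrics` (names become row labels),
#'   or a single `query_metrics`.
#' @param path output CSV path.
#' @return (invisibly) the report data.frame.
#' @export
write_metrics_report <- function(results, path) {
  if (inherits(results, "query_metrics")) results <- list(query = results)
  rows <- do.call(rbind, lapply(names(results), function(nm) {
    m <- results[[nm]]
    d <- metric_display(m)
    ci_str <- function(ci) {
      if (anyNA(ci)) "" else sprintf("%d-%d%%", ci[1], ci[2])
    }
    data.frame(query = nm, tp = m$confusion$tp, fp = m$confusion$fp,
               fn = m$confusion$fn, tn = m$confusion$tn,
               sensitivity_pct = d$sensitivity_pct,
               sensitivity_ci = ci_str(d$sensitivity_ci_pct),
               specificity_pct = d$specificity_pct,
               specificity_ci = ci_str(d$specificity_ci_pct),
               ppv_pct = d$ppv_pct, ppv_ci = ci_str(d$ppv_ci_pct),
               f1 = d$f1, n = m$n_evaluated,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}

#' Benchmark confusion matrices for the four classification queries
#'
#' Published operating points of the four computerized queries (relevant
#' image type, surveillance indication, suspicious findings, definitive
#' recurrence findings) evaluated against a fully manually abstracted
#' gold-standard cohort of 361 lung-cancer patients, plus the per-image-type
#' breakdown of the image-type query. Shipped as plain CSV so the
#' evaluation arithmetic can be reproduced without access to the restricted
#' report corpus itself.
#'
#' @return data.frame with columns `query`, `label`, `tp`, `fp`, `fn`, `tn`.
#' @export
benchmark_confusions <- function() {
  path <- system.file("extdata", "benchmark_confusions.csv",
                      package = "radsift")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Benchmark abstraction timing summaries
#'
#' Published timing summaries comparing fully manual chart abstraction with
#' semi-automated abstraction (image-type query pre-filter + manual
#' review): per-patient minutes and per-report seconds (median, IQR) and
#' reports per patient (mean, SD) for each arm.
#'
#' @return data.frame with columns `metric`, `statistic`, `manual`,
#'   `semi_automated`.
#' @export
benchmark_timing <- function() {
  path <- system.file("extdata", "benchmark_timing.csv",
                      package = "radsift")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
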