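#' Percent reduction between two medians
#'
#' `100 * (manual - semi) / manual`: the share of abstraction time saved by
#' the semi-automated workflow relative to fully manual abstraction.
#'
#' @param manual,semi non-negative summary values (typically medians).
#' @return percent reduction (positive when `semi < manual`).
#' @export
#' @examples
#' percent_reduction(21.5, 6.9)  # ~68
percent_reduction <- function(manual, semi) {
  stopifnot(manual >= 0, semi >= 0)
  if (manual == 0) stop("manual value is 0; reduction undefined",
                        call. = FALSE)
  100 * (manual - semi) / manual
}

#' One arm of a timing comparison
#'
#' @param minutes_per_patient numeric vector, abstraction minutes per
#'   patient.
#' @param seconds_per_report optional numeric vector, seconds per report.
#' @param reports_per_patient optional numeric vector, reports reviewed per
#'   patient.
#' @return an object of class `timing_arm`.
#' @export
timing_arm <- function(minutes_per_patient, seconds_per_report = NULL,
                       reports_per_patient = NULL) {
  if (!length(minutes_per_patient)) {
    stop("timing arm must contain at least one patient", call. = FALSE)
  }
  stopifnot(all(minutes_per_patient >= 0))
  structure(list(minutes_per_patient = as.numeric(minutes_per_patient),
                 seconds_per_report = as.numeric(seconds_per_report),
                 reports_per_patient = as.numeric(reports_per_patient)),
            class = "timing_arm")
}

# Rank-sum comparison: exact distribution for small untied samples, normal
# approximation (with tie correction, as wilcox.test applies) otherwise.
ranksum_p <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("rank-sum test needs at least 2 samples per arm", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && max(length(x), length(y)) <= 20L
  stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value
}

#' Compare manual and semi-automated abstraction timing
#'
#' Medians and IQRs per arm for per-patient minutes and per-report seconds,
#' two-sided Wilcoxon rank-sum p-values for the time variables, a Welch
#' two-sample t-test for reports per patient, and the percent reduction of
#' medians. With fewer than 2 samples in an arm the summaries are still
#' reported but the tests error unless `tests = FALSE`.
#'
#' @param manual,semi `timing_arm` objects.
#' @param tests run the hypothesis tests (default `TRUE`).
#' @return an object of class `timing_comparison` with a `table` of
#'   summaries and fields `p_minutes`, `p_seconds`, `p_reports`,
#'   `reduction_minutes_pct`, `reduction_seconds_pct`.
#' @export
compare_timing <- function(manual, semi, tests = TRUE) {
  stopifnot(inherits(manual, "timing_arm"), inherits(semi, "timing_arm"))
  summarise <- function(x) {
    c(median = unname(stats::median(x)), iqr = stats::IQR(x))
  }
  man_min <- summarise(manual$minutes_per_patient)
  semi_min <- summarise(semi$minutes_per_patient)
  out <- list(
    table = data.frame(
      metric = "minutes_per_patient",
      manual_median = man_min["median"], manual_iqr = man_min["iqr"],
      semi_median = semi_min["median"], semi_iqr = semi_min["iqr"],
      row.names = NULL),
    reduction_minutes_pct = percent_reduction(man_min[["median"]],
                                              semi_min[["median"]]),
    reduction_seconds_pct = NA_real_,
    p_minutes = NA_real_, p_seconds = NA_real_, p_reports = NA_real_,
    reports_summary = NULL)
  if (length(manual$seconds_per_report) && length(semi$seconds_per_report)) {
    man_s <- summarise(manual$seconds_per_report)
    semi_s <- summarise(semi$seconds_per_report)
    out$table <- rbind(out$table, data.frame(
      metric = "seconds_per_report",
      manual_median = man_s["median"], manual_iqr = man_s["iqr"],
      semi_median = semi_s["median"], semi_iqr = semi_s["iqr"],
      row.names = NULL))
    out$reduction_seconds_pct <- percent_reduction(man_s[["median"]],
                                                   semi_s[["median"]])
  }
  if (length(manual$reports_per_patient) &&
      length(semi$reports_per_patient)) {
    out$reports_summary <- data.frame(
      arm = c("manual", "semi_automated"),
      mean = c(mean(manual$reports_per_patient),
               mean(semi$reports_per_patient)),
      sd = c(stats::sd(manual$reports_per_patient),
             stats::sd(semi$reports_per_patient)))
  }
  if (tests) {
    out$p_minutes <- ranksum_p(manual$minutes_per_patient,
                               semi$minutes_per_patient)
    if (length(manual$seconds_per_report) &&
        length(semi$seconds_per_report)) {
      out$p_seconds <- ranksum_p(manual$seconds_per_report,
                                 semi$seconds_per_report)
    }
    if (length(manual$reports_per_patient) > 1L &&
        length(semi$reports_per_patient) > 1L) {
      out$p_reports <- stats::t.test(manual$reports_per_patient,
                                     semi$reports_per_patient)$p.value
    }
  }
  structure(out, class = "timing_comparison")
}

#' @export
print.timing_comparison <- function(x, ...) {
  cat("<timing_comparison>\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("  reduction in minutes/patient: %.0f%% (rank-sum p=%s)\n",
              x$reduction_minutes_pct, format.pval(x$p_minutes)))
  if (!is.na(x$reduction_seconds_pct)) {
    cat(sprintf("  reduction in seconds/report:  %.0f%% (rank-sum p=%s)\n",
                x$reduction_seconds_pct, format.pval(x$p_seconds)))
  }
  if (!is.null(x$reports_summary)) {
    cat(sprintf("  reports/patient: %.2f vs %.2f (t-test p=%s)\n",
                x$reports_summary$mean[1], x$reports_summary$mean[2],
                format.pval(x$p_reports)))
  }
  invisible(x)
}
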