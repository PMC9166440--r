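test_that("confusion counts the four cells over aligned doc ids", {
  g <- c(a = "x", b = "x", c = "y", d = "y")
  p <- c(a = "x", b = "y", c = "x", d = "y")
  cm <- confusion(g, p, positive = "x")
  expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]),
               c(tp = 1L, fn = 1L, fp = 1L, tn = 1L))
  ident <- confusion(g, g, positive = "x")
  expect_equal(ident$fp + ident$fn, 0L)
  expect_error(confusion(g, p[1:3], positive = "x"), "different doc_ids")
})

test_that("confusion cells equal an explicit per-document loop", {
  set.seed(88)
  ids <- sprintf("d%03d", 1:500)
  g <- stats::setNames(sample(c("pos", "neg", "other"), 500, TRUE), ids)
  p <- stats::setNames(sample(c("pos", "neg", "other"), 500, TRUE), ids)
  cm <- confusion(g, p, positive = "pos")
  tp <- fp <- fn <- tn <- 0L
  for (id in ids) {
    gp <- g[[id]] == "pos"; pp <- p[[id]] == "pos"
    if (gp && pp) tp <- tp + 1L else if (!gp && pp) fp <- fp + 1L
    else if (gp && !pp) fn <- fn + 1L else tn <- tn + 1L
  }
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
               c(tp = tp, fp = fp, fn = fn, tn = tn))
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, 500L)
})

test_that("metric formulas match hand-computed fractions and rounding", {
  m <- metrics(confusion_counts(tp = 2548, fp = 133, fn = 463, tn = 47))
  expect_equal(m$sensitivity, 2548 / (2548 + 463))
  expect_equal(m$specificity, 47 / (47 + 133))
  expect_equal(m$ppv, 2548 / (2548 + 133))
  d <- metric_display(m)
  expect_equal(d$sensitivity_pct, 85)
  expect_equal(d$ppv_pct, 95)
  expect_equal(d$specificity_pct, 26)
  expect_equal(d$f1, 0.90)
  # perfect classifier
  mp <- metrics(confusion_counts(tp = 10, fp = 0, fn = 0, tn = 5))
  expect_equal(c(mp$sensitivity, mp$specificity, mp$ppv, mp$f1),
               c(1, 1, 1, 1))
})

test_that("F1 is the harmonic mean of sensitivity and PPV", {
  set.seed(3)
  for (i in 1:200) {
    cm <- confusion_counts(tp = sample(0:50, 1), fp = sample(0:50, 1),
                           fn = sample(0:50, 1), tn = sample(0:50, 1))
    m <- metrics(cm)
    if (!is.na(m$f1)) {
      expect_equal(m$f1,
                   2 * m$sensitivity * m$ppv / (m$sensitivity + m$ppv),
                   tolerance = 1e-12)
    }
  }
})

test_that("zero denominators are flagged as undefined, not coerced", {
  m <- metrics(confusion_counts(tp = 0, fp = 5, fn = 0, tn = 10))
  expect_true("sensitivity" %in% m$undefined)
  expect_true(is.na(m$sensitivity))
  m2 <- metrics(confusion_counts(tp = 4, fp = 0, fn = 2, tn = 0))
  expect_true("specificity" %in% m2$undefined)
  expect_false("ppv" %in% m2$undefined)
})

test_that("confidence intervals match stats-package reference intervals", {
  cases <- expand.grid(x = c(0, 1, 17, 50, 99, 100), n = c(100))
  for (i in seq_len(nrow(cases))) {
    x <- cases$x[i]; n <- cases$n[i]
    m_cp <- metrics(confusion_counts(tp = x, fp = 0, fn = n - x, tn = 0),
                    ci_method = "clopper_pearson")
    ref <- stats::binom.test(x, n)$conf.int
    expect_equal(m_cp$sensitivity_ci, as.numeric(ref), tolerance = 1e-10)
    m_w <- metrics(confusion_counts(tp = x, fp = 0, fn = n - x, tn = 0),
                   ci_method = "wilson")
    refw <- suppressWarnings(stats::prop.test(x, n, correct = FALSE)$conf.int)
    expect_equal(m_w$sensitivity_ci, as.numeric(refw), tolerance = 1e-8)
  }
})

test_that("interval coverage is near nominal on simulated binomials", {
  set.seed(2718)
  for (p in c(0.1, 0.5, 0.9)) {
    for (n in c(50, 500)) {
      x <- stats::rbinom(2000, n, p)
      lo <- ifelse(x == 0, 0, stats::qbeta(0.025, x, n - x + 1))
      hi <- ifelse(x == n, 1, stats::qbeta(0.975, x + 1, n - x))
      # the package computes the same exact interval; spot-check then cover
      m <- metrics(confusion_counts(tp = x[1], fp = 0, fn = n - x[1], tn = 0))
      expect_equal(m$sensitivity_ci, c(lo[1], hi[1]), tolerance = 1e-12)
      coverage <- mean(lo <= p & p <= hi)
      expect_gte(coverage, 0.93)
    }
  }
})

test_that("per-type metrics are one-vs-rest confusions per label", {
  ids <- sprintf("d%d", 1:9)
  g <- stats::setNames(rep(c("pet", "ct_chest", "chest_xray"), each = 3), ids)
  tab <- per_type_metrics(g, g)
  expect_equal(tab$sensitivity_pct, rep(100, 3))
  expect_equal(tab$fp, rep(0L, 3))
  # injected 10% false negatives pull sensitivity toward 90%
  set.seed(11)
  ids <- sprintf("d%d", 1:4000)
  g <- stats::setNames(sample(c("pet", "ct_chest"), 4000, TRUE), ids)
  p <- g
  flip <- stats::runif(4000) < 0.1
  p[flip] <- ifelse(g[flip] == "pet", "null", "null")
  tab <- per_type_metrics(g, p)
  expect_true(all(abs(tab$sensitivity_pct - 90) <= 3))
})

test_that("metrics reports round-trip through the CSV writer", {
  res <- list(image_type = metrics(confusion_counts(2548, 133, 463, 47)),
              surveillance = metrics(confusion_counts(690, 292, 264, 1763)))
  path <- withr::local_tempfile(fileext = ".csv")
  rows <- write_metrics_report(res, path)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$query, c("image_type", "surveillance"))
  expect_equal(back$sensitivity_pct, c(85, 72))
  expect_equal(back$f1, c(0.90, 0.71))
})
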