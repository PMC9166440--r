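---
title: "Semi-automated chart abstraction with rule-based report retrieval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-automated chart abstraction with rule-based report retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsift)
```

## The workflow this package implements

Coding post-treatment imaging in lung-cancer cohorts has three axes per
report — image type, indication, findings — and free-text radiology reports
as the only source. radsift implements the semi-automated alternative to
fully manual abstraction: computerized queries retrieve and pre-classify
reports, a human codes what the filter keeps. The package has four layers:
a query engine over an inverted index, rule sets mapping labels to queries,
an evaluation harness, and a synthetic corpus generator that stands in for
restricted clinical data.

## Query semantics

**Tokenization.** Text is lower-cased and split on any non-alphanumeric
run; offsets map back to the original string. There is deliberately no
stemming and no stop-word list: the negation tokens "no" and "not" must
survive tokenization for span exclusion to work, and hyphenated forms
("follow-up") split into searchable words.

**Phrase queries** match contiguous normalized token runs. **Boolean
queries** are set algebra over per-document results (OR = union,
AND = intersection); retrieval is purely Boolean, with no ranking — the
abstractor sees every hit. **Span queries** take ≥2 term groups and fire
where at least one term from each group co-occurs in a window of at most
`window` tokens (default 10), first hit to last hit inclusive. Groups are
unordered by default — "within a 10-word span" does not promise an order —
with an `ordered` flag for the stricter reading. Matches are *minimal*
(non-extendable) spans, which prevents double counting in snippets and
evaluation.

**Negation.** A candidate span is invalidated when a negation token could
share a `window`-wide span with the matched terms: a negation at position
`p` kills span `[a, b]` whenever `max(b, p) − min(a, p) + 1 ≤ window`. The
neighbourhood test matters: in "no findings concerning for recurrence" the
minimal span is `[concerning … recurrence]` and the "no" sits *outside* it,
yet the statement is plainly negated — the window-proximity rule excludes
it, while "no" more than ten tokens upstream of a trigger pair does not.
Two scopes are available: `match` (default) discards only the negated span,
so a report with a separate affirmative statement is still retrieved;
`document` discards the whole report when any candidate span is negated —
the strict reading of "reports with no/not in the span were excluded". The
default is the permissive scope because a genuinely affirmative second
statement should not be silenced by an unrelated negation; the switch is
one flag in the rule file.

**Index correctness.** The inverted index is used only to prune candidate
documents; matching always runs on the cached token streams. The test suite
holds the indexed path equal to a brute-force per-document evaluator over
hundreds of random corpora and query trees, and span matching equal to
exhaustive window enumeration.

## Rule sets

Rules live in plain-text files (`inst/rules/`), one per axis, in a small
DSL: `label: OR("phrase"; term; SPAN(groups=[a|b, c]; window=10;
not=[no,not]))`. The shipped defaults follow the structure used in
rule-based radiology abstraction — per-type phrase ORs for image type, a
surveillance phrase rule, and two-group span rules pairing a hedge term
(worrisome/concerning/suspicious) or an assertion term
(consistent/definite/compatible/…) with a disease term
(recurrence/metastatic/…). The exact published term lists for this task are
not publicly available, so the shipped lexicons are deliberately small,
editable approximations; every term list is expected to be tuned to a local
corpus. Composite studies are listed before their components
(`ct_chest_abdomen_pelvis` before `ct_chest`) because rule order breaks
ties: the first firing label wins and the conflict is reported, since a
single OR-of-everything image query cannot itself say *which* type it
matched.

Rules see the concatenated title and body — the whole scope of the
document — and nothing else; classification is a pure function of text.

## The synthetic cohort

The generator emulates a manually abstracted gold-standard cohort: 361
patients and ≈3,191 reports, of which ≈5.6% are irrelevant "null" studies
(foot X-rays, pelvic ultrasounds) and the rest carry the cohort's printed
marginals — 43.8% chest X-ray and 30.0% CT chest among annotated image
types, 31.7% surveillance among indications, 11.0% suspicious and 3.7%
recurrence among findings. Reports per patient are drawn from a normal
floored at 1 with mean 8.8 and sd 4.4, chosen so the expected total matches
the cohort's ≈3,191 reports (the published timing substudy's 12.75 ± 10.50
reports/patient describes a different, smaller cohort and is used as the
default in timing simulations instead).

Two noise dials control how visible the truth is to the rules:

- `phrase_noise` (default 0.15): per axis, the probability that a report
  phrases itself outside the rule lexicon ("THORACIC IMAGING EXAMINATION"
  instead of a recognisable chest X-ray title). These reports are false
  negatives for any rule set that does not learn the paraphrase — our
  stand-in for the true linguistic variety of dictated reports, whose real
  rate is unknowable without the restricted data.
- `negation_rate` (default 0.3): the probability that a benign or
  nonspecific report states its findings as a negated trigger ("No interval
  change worrisome for recurrence"), putting "no"/"not" within the 10-token
  window of a trigger pair. Radiologists negate constantly; a third is a
  realistic, deliberately conservative choice. Every generated negated
  mention must be invisible to the default span rules — a property the test
  suite asserts over the whole corpus.

The templates are formulaic by design: the corpus tests retrieval logic,
not linguistic realism. Consequently a perfect score here does **not**
predict performance on real reports — it certifies the machinery
(tokenization, phrase/span matching, negation exclusion, tie-breaking),
while `phrase_noise` models, crudely, the out-of-lexicon failure mode that
dominates in practice. With both dials at zero the default rules classify
every axis with sensitivity = PPV = 1 on a ≈3,000-report corpus; that
perfect-world check is part of the test suite.

`inject_errors()` turns the clean corpus into one with a chosen operating
point: it computes how many detected positives to paraphrase into false
negatives and how many negatives to seed with trigger phrases so the
expected sensitivity and PPV equal the targets, errors when a target is
infeasible for the corpus size, touches only text (never gold labels), and
is deterministic given its seed. Calibration is exact up to rounding
because the rewrite counts are computed, not sampled rates; the residual
variability across seeds comes from which reports are rewritten.

## Evaluation conventions

Metrics follow the standard definitions (sensitivity `TP/(TP+FN)`,
specificity `TN/(TN+FP)`, PPV `TP/(TP+FP)`, F1 the harmonic mean of
sensitivity and PPV, computed from the *unrounded* proportions). Display
rounding mirrors clinical-performance tables — whole percents, F1 to two
decimals — with raw values retained in the object. Zero denominators yield
an explicit `undefined` marker, never a silent 0 or 1.

Confidence intervals default to Clopper–Pearson exact (conservative and
conventional for test-performance reporting; the benchmark tables this
package reproduces do not name their method), with Wilson score as the
alternative; both are cross-checked in the tests against
`stats::binom.test()` and `stats::prop.test()`, and empirical coverage is
verified by simulation.

Timing comparisons report medians and IQRs per arm, a two-sided Wilcoxon
rank-sum test for the time variables (exact for small untied samples,
normal approximation with tie correction otherwise), a Welch t-test for
reports per patient (the variances of the two arms have no reason to be
equal), and `100·(manual − semi)/manual` percent reductions of the medians.
The human timing measurements themselves are input data, not something this
package can reproduce; `compare_timing()` is validated by the
percent-reduction identity on the published medians (21.5 → 6.9 min/patient
= 68%) and by a seeded Monte-Carlo power check against an independently
coded rank-sum statistic.

## Numerical and design choices

- Dates are normalized to ISO-8601 on ingest under a strict
  parse-and-reformat round trip, so an ambiguous dialect can never be
  half-parsed.
- `"null"` is serialized as a literal string, keeping "irrelevant report"
  distinct from "unannotated".
- JSONL is the canonical record format (report text contains commas and
  newlines); CSV is supported with a quoted text field.
- Multi-fire conflicts are resolved first-listed-wins *and* surfaced, never
  silently.
- The inverted index is built in memory per invocation and is not a
  persisted artifact; the CLI therefore has no separate `index` command —
  `query`, `classify` and `review-queue` build it on the fly.
- Problem sizes in the test suite (≈3,000-report corpora for the end-to-end
  checks, 200 random corpora for the oracle-equivalence property, 5 seeds
  for operating-point recovery) were chosen as the smallest sizes at which
  the binomial tolerances quoted in the tests are meaningful.

## Known limitations

- Rule quality is bounded by the lexicon: the shipped term lists are
  reconstructions, not a validated clinical vocabulary, and real-world
  sensitivity will track how well they are tuned.
- Negation handling is window-proximity only; scoped negation ("no change
  in the previously noted recurrence") and hedged affirmations are beyond
  a two-group span rule, which is precisely why the workflow keeps a human
  in the loop for indication and findings.
- The generator's English is templated; it cannot surface tokenizer or
  rule failures that only occur in messy dictation (abbreviations, section
  headers, OCR noise).
- Evaluation is report-level throughout; patient-level aggregation is out
  of scope.
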