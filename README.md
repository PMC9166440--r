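# radsift

Rule-based retrieval and semi-automated abstraction of free-text radiology
reports.

## The problem

Surveillance research in treated lung-cancer cohorts needs every imaging
study coded for **image type** (chest X-ray, CT chest, PET, ...), **study
indication** (surveillance, symptoms, follow-up of a prior abnormality,
...) and **findings** (benign, nonspecific, suspicious for recurrence,
definitive recurrence, ...). Fully manual chart abstraction is accurate but
slow; fully automated classifiers are fast but not accurate enough for
indication and findings. The semi-automated middle ground uses computerized
queries as a *pre-processing filter*: a high-precision query retrieves the
relevant reports (with highlighted snippets), and a human abstractor codes
only what survives the filter.

radsift implements that workflow end to end:

- **Query engine** — a tokenizer, an inverted index, and Boolean / phrase /
  span queries with *negation exclusion*. A span query
  `SPAN(groups=[worrisome|concerning, recurrence|metastatic]; window=10;
  not=[no,not])` fires where one term from each group co-occurs within a
  10-token window; the candidate span is discarded when "no" or "not" falls
  within the same window, so "**no** findings concerning for recurrence"
  does not match.
- **Rule sets** — editable text configs mapping labels to queries, one file
  per axis, with shipped defaults (per-type phrase ORs for image type, a
  surveillance phrase rule, two-group span rules for suspicious/recurrence
  findings).
- **Evaluation** — 2×2 confusions and sensitivity `TP/(TP+FN)`, specificity
  `TN/(TN+FP)`, PPV `TP/(TP+FP)`,
  `F1 = 2·(sens·PPV)/(sens+PPV)`, with Clopper–Pearson (default) or Wilson
  confidence intervals, one-vs-rest per-label breakdowns, and
  Wilcoxon/t-test timing comparisons with percent-reduction summaries.
- **Synthetic cohort generator** — a seedable generator emulating a
  manually abstracted gold-standard cohort (361 patients, ≈3,200 reports,
  43.8% chest X-ray, 31.7% surveillance, 11.0% suspicious, ≈5.6% irrelevant
  "null" reports), with controllable negation and paraphrase-noise rates,
  plus `inject_errors()` to force any target sensitivity/PPV operating
  point. Everything is testable without restricted clinical data.

## Worked example

```r
library(radsift)

# Score a published 2x2 confusion matrix for the image-type query
metrics(confusion_counts(tp = 2548, fp = 133, fn = 463, tn = 47))
#> <query_metrics> n=3191 (clopper_pearson CI)
#>   sensitivity: 85% (83-86%)
#>   specificity: 26% (20-33%)
#>   PPV:         95% (94-96%)
#>   F1:          0.90

# Simulate a small annotated cohort and run the relevance pre-filter
corp <- generate_corpus(generator_config(n_patients = 50, seed = 7))
corp
#> <report_corpus> 491 reports, 50 patients, 491 annotations
flagged <- classify_relevance(corp)
length(flagged)
#> [1] 383

# How good is the filter on this noisy corpus? (default phrase_noise = 0.15
# makes ~15% of reports invisible to the rules, so sensitivity < 100%)
gold <- annotations(corp, "gold")
gv <- setNames(ifelse(gold$image_type != "null", "relevant", "null"), gold$doc_id)
pv <- setNames(ifelse(gold$doc_id %in% flagged, "relevant", "null"), gold$doc_id)
metrics(confusion(gv, pv, positive = "relevant"))
#> <query_metrics> n=491 (clopper_pearson CI)
#>   sensitivity: 83% (79-86%)
#>   specificity: 100% (87-100%)
#>   PPV:         100% (99-100%)
#>   F1:          0.90
```

Sensitivity is the share of truly relevant reports the filter retrieved;
PPV is the share of retrieved reports that were truly relevant. Here every
miss comes from the injected paraphrase noise — reports whose titles avoid
the rule lexicon — which is exactly the failure mode rule-based retrieval
has on real dictation variability.

The same machinery is scriptable via the installed `radsift` executable:
`simulate`, `query`, `classify`, `review-queue`, `evaluate`,
`timing-compare` (run `radsift` with no arguments for usage).

## Package layout

- `R/` — corpus model and I/O, tokenizer, inverted index, query matching,
  rule DSL, classifiers, evaluation, timing, synthetic generator, CLI.
- `inst/rules/` — shipped default rule files (editable).
- `inst/extdata/` — benchmark confusion counts and timing summaries (CSV).
- `vignettes/semi-automated-abstraction.Rmd` — methods: query semantics,
  negation scope, generator design, evaluation conventions, limitations.
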