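# Synthetic radiology report generator.
#
# The templates are deliberately formulaic English over a small lexicon: the
# corpus exists to exercise retrieval logic (phrase hits, span windows,
# negation) under known gold labels, not to imitate clinical narrative.
# Every affirmative suspicious/recurrence findings sentence carries at least
# one default-rule trigger pair; every negated variant places "no"/"not"
# within the 10-token window of the trigger pair so the negation exclusion
# is exercised on each generated negative mention.

report_lexicon <- function() {
  list(
    titles = list(
      bone_scan = c("WHOLE BODY BONE SCAN",
                    "BONE SCAN THREE PHASE"),
      chest_xray = c("CHEST X RAY PA AND LATERAL",
                     "CHEST RADIOGRAPH PORTABLE",
                     "PA AND LATERAL CHEST RADIOGRAPH"),
      ct_abdomen_pelvis = c("CT ABDOMEN AND PELVIS WITH CONTRAST",
                            "CT OF THE ABDOMEN AND PELVIS"),
      ct_chest = c("CT CHEST WITH CONTRAST",
                   "CT OF THE CHEST WITHOUT CONTRAST",
                   "CT THORAX HIGH RESOLUTION"),
      ct_chest_abdomen_pelvis = c("CT CHEST ABDOMEN AND PELVIS WITH CONTRAST",
                                  "CT OF THE CHEST ABDOMEN AND PELVIS"),
      ct_head = c("CT HEAD WITHOUT CONTRAST",
                  "CT OF THE HEAD"),
      mri_body = c("MRI BODY WITH CONTRAST",
                   "MRI OF THE ABDOMEN"),
      mri_brain = c("MRI BRAIN WITH AND WITHOUT CONTRAST",
                    "MRI OF THE BRAIN"),
      pet = c("PET CT SKULL BASE TO THIGH",
              "PET SCAN WHOLE BODY"),
      null = c("X RAY LEFT FOOT",
               "X RAY LUMBAR SPINE",
               "ULTRASOUND PELVIS",
               "ULTRASOUND THYROID",
               "DEXA BONE DENSITY STUDY")),
    # out-of-lexicon paraphrase titles: invisible to the default rules
    noise_titles = c("THORACIC IMAGING EXAMINATION",
                     "CROSS SECTIONAL IMAGING EXAMINATION",
                     "NUCLEAR MEDICINE EXAMINATION",
                     "MAGNETIC RESONANCE EXAMINATION",
                     "RADIOLOGY EXAMINATION OUTSIDE PROTOCOL"),
    indication = list(
      surveillance = c(
        "INDICATION: Routine surveillance imaging after treatment of non small cell lung cancer.",
        "INDICATION: Surveillance examination following lung cancer resection."),
      symptomatic = c(
        "INDICATION: New cough and chest wall pain.",
        "INDICATION: Evaluation of dyspnea and fatigue."),
      followup_abnormal_chest = c(
        "INDICATION: Follow up of abnormality on prior chest imaging."),
      followup_abnormal_other = c(
        "INDICATION: Follow up of abnormality on prior abdominal imaging."),
      other = c(
        "INDICATION: Preoperative evaluation.",
        "INDICATION: Staging evaluation requested by oncology."),
      unknown = c(
        "INDICATION: See electronic order.")),
    indication_noise = c(
      "INDICATION: Asymptomatic interval assessment after lobectomy."),
    findings = list(
      suspicious = c(
        "FINDINGS: New 12 mm nodule worrisome for recurrence.",
        "FINDINGS: Enlarging right lower lobe opacity concerning for metastatic disease.",
        "FINDINGS: Findings suspicious for recurrent disease."),
      recurrence = c(
        "FINDINGS: Findings consistent with recurrence of malignancy in the right hilum.",
        "FINDINGS: Biopsy proven metastatic disease with definite interval progression.",
        "FINDINGS: Compatible with recurrent tumor at the resection margin."),
      benign = c(
        "FINDINGS: Stable postsurgical changes with calcified granuloma unchanged.",
        "FINDINGS: Benign appearing scarring at the resection site."),
      nonspecific = c(
        "FINDINGS: Scattered bibasilar atelectasis of indeterminate significance.",
        "FINDINGS: Mild interstitial prominence, nonspecific."),
      second_primary_lung = c(
        "FINDINGS: New left upper lobe primary lung carcinoma is favored."),
      second_primary_other = c(
        "FINDINGS: New renal mass favored to represent a separate primary tumor."),
      other_unrelated = c(
        "FINDINGS: Incidental cholelithiasis without acute process.",
        "FINDINGS: Degenerative change of the thoracic spine.")),
    findings_negated = list(
      benign = c(
        "FINDINGS: No interval change worrisome for recurrence. Stable postsurgical appearance.",
        "FINDINGS: No evidence concerning for recurrence or metastatic disease."),
      nonspecific = c(
        "FINDINGS: Scattered opacities, not concerning for metastatic disease.",
        "FINDINGS: Subcentimeter nodule, not definite for recurrence, attention on follow up.")),
    findings_noise = list(
      suspicious = c(
        "FINDINGS: Ominous interval change suggestive of tumor regrowth."),
      recurrence = c(
        "FINDINGS: Unequivocal tumor regrowth at the surgical bed.")),
    null_body = c(
      "FINDINGS: Degenerative changes. IMPRESSION: Mild osteoarthritis.",
      "FINDINGS: Unremarkable study. IMPRESSION: Within normal limits."),
    technique = c(
      "TECHNIQUE: Standard departmental protocol.",
      "TECHNIQUE: Images acquired per routine."),
    comparison = c(
      "COMPARISON: Prior examination reviewed.",
      "COMPARISON: Available prior studies reviewed."))
}

table1_image_mix <- function() {
  counts <- c(bone_scan = 23, chest_xray = 1320, ct_abdomen_pelvis = 127,
              ct_chest = 902, ct_chest_abdomen_pelvis = 123, ct_head = 149,
              mri_body = 58, mri_brain = 42, pet = 267, null = 180)
  counts / sum(counts)
}

table1_indication_mix <- function() {
  counts <- c(surveillance = 954, symptomatic = 649,
              followup_abnormal_chest = 244, followup_abnormal_other = 30,
              other = 480, unknown = 652)
  counts / sum(counts)
}

table1_findings_mix <- function() {
  counts <- c(suspicious = 331, recurrence = 110, benign = 959,
              nonspecific = 1019, second_primary_lung = 14,
              second_primary_other = 11, other_unrelated = 564)
  counts / sum(counts)
}

check_mix <- function(mix, expected_names, what) {
  if (is.null(names(mix)) || !setequal(names(mix), expected_names) ||
      length(mix) != length(expected_names)) {
    stop(sprintf("%s must be a named probability vector over: %s", what,
                 paste(expected_names, collapse = ", ")), call. = FALSE)
  }
  if (any(mix < 0) || any(mix > 1) || abs(sum(mix) - 1) > 1e-9) {
    stop(sprintf("%s must lie in [0,1] and sum to 1", what), call. = FALSE)
  }
  mix[expected_names]
}

#' Configuration for the synthetic report generator
#'
#' Defaults emulate a manually abstracted gold-standard cohort of 361
#' lung-cancer patients: the image-type mix (43.8% chest X-ray, 30.0% CT
#' chest, ...), indication mix (31.7% surveillance) and findings mix (11.0%
#' suspicious, 3.7% recurrence), with irrelevant "null" reports at the rate
#' implied by that cohort (180/3191, about 5.6%). Reports per patient are
#' drawn from a normal distribution floored at 1, with the default mean/sd
#' chosen so the expected corpus size matches the cohort total of about
#' 3,191 reports.
#'
#' @param n_patients number of patients (default 361).
#' @param reports_per_patient numeric `c(mean, sd)` of the per-patient
#'   report-count distribution before flooring at 1 (default `c(8.8, 4.4)`).
#' @param image_type_mix probability vector over the nine image types plus
#'   `"null"`; default from the gold-cohort composition.
#' @param indication_mix probability vector over the six indications.
#' @param findings_mix probability vector over the seven findings labels.
#' @param negation_rate probability that a benign/nonspecific report phrases
#'   its findings as a negated trigger ("No findings concerning for
#'   recurrence"), exercising the negation exclusion. Default 0.3.
#' @param phrase_noise probability (per axis) that a report uses an
#'   out-of-lexicon paraphrase invisible to the default rules. Default 0.15.
#' @param seed integer RNG seed stored in the config (default 101).
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 361L,
                             reports_per_patient = c(mean = 8.8, sd = 4.4),
                             image_type_mix = table1_image_mix(),
                             indication_mix = table1_indication_mix(),
                             findings_mix = table1_findings_mix(),
                             negation_rate = 0.3,
                             phrase_noise = 0.15,
                             seed = 101L) {
  stopifnot(n_patients >= 1, length(reports_per_patient) == 2L,
            reports_per_patient[2] >= 0,
            negation_rate >= 0, negation_rate <= 1,
            phrase_noise >= 0, phrase_noise <= 1)
  structure(list(
    n_patients = as.integer(n_patients),
    reports_per_patient = stats::setNames(as.numeric(reports_per_patient),
                                          c("mean", "sd")),
    image_type_mix = check_mix(image_type_mix, axis_labels("image_type"),
                               "image_type_mix"),
    indication_mix = check_mix(indication_mix,
                               setdiff(axis_labels("indication"), "null"),
                               "indication_mix"),
    findings_mix = check_mix(findings_mix,
                             setdiff(axis_labels("findings"), "null"),
                             "findings_mix"),
    negation_rate = negation_rate,
    phrase_noise = phrase_noise,
    seed = as.integer(seed)),
    class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(paste0("<generator_config> %d patients, reports/patient ",
                     "~ N(%.2f, %.2f) floored at 1\n"),
              x$n_patients, x$reports_per_patient["mean"],
              x$reports_per_patient["sd"]))
  cat(sprintf("  negation_rate=%.2f phrase_noise=%.2f seed=%d\n",
              x$negation_rate, x$phrase_noise, x$seed))
  invisible(x)
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

pick <- function(choices) {
  if (length(choices) == 1L) choices else choices[sample.int(length(choices), 1L)]
}

#' Generate a synthetic annotated report corpus
#'
#' Deterministic given the seed; every document carries gold labels on all
#' three axes (irrelevant reports are `"null"` on every axis), and label
#' frequencies converge to the configured mixes as the corpus grows. The
#' returned corpus carries a `provenance` attribute recording, per document,
#' whether its title/indication/findings used an out-of-lexicon paraphrase
#' and whether its findings mention is negated — useful for verifying rule
#' behaviour in tests.
#'
#' @param config a [generator_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return a `report_corpus` with gold annotations.
#' @export
generate_corpus <- function(config = generator_config(), seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(seed, {
    lex <- report_lexicon()
    n_rep <- pmax(1L, as.integer(round(stats::rnorm(
      config$n_patients, config$reports_per_patient["mean"],
      config$reports_per_patient["sd"]))))
    total <- sum(n_rep)
    patient <- rep(sprintf("P%04d", seq_len(config$n_patients)), n_rep)
    dates <- as.Date("2009-01-01") + unlist(lapply(n_rep, function(k) {
      sort(sample.int(2920L, k, replace = TRUE))
    }), use.names = FALSE)
    image <- sample(names(config$image_type_mix), total, replace = TRUE,
                    prob = config$image_type_mix)
    is_null <- image == "null"
    indication <- ifelse(is_null, "null",
                         sample(names(config$indication_mix), total,
                                replace = TRUE, prob = config$indication_mix))
    findings <- ifelse(is_null, "null",
                       sample(names(config$findings_mix), total,
                              replace = TRUE, prob = config$findings_mix))
    title_noise <- !is_null & stats::runif(total) < config$phrase_noise
    ind_noise <- indication == "surveillance" &
      stats::runif(total) < config$phrase_noise
    find_noise <- findings %in% c("suspicious", "recurrence") &
      stats::runif(total) < config$phrase_noise
    negated <- findings %in% names(lex$findings_negated) &
      stats::runif(total) < config$negation_rate

    title <- character(total)
    text <- character(total)
    for (i in seq_len(total)) {
      if (is_null[i]) {
        title[i] <- pick(lex$titles$null)
        text[i] <- pick(lex$null_body)
        next
      }
      title[i] <- if (title_noise[i]) pick(lex$noise_titles)
                  else pick(lex$titles[[image[i]]])
      ind_sentence <- if (ind_noise[i]) pick(lex$indication_noise)
                      else pick(lex$indication[[indication[i]]])
      find_sentence <- if (find_noise[i]) {
        pick(lex$findings_noise[[findings[i]]])
      } else if (negated[i]) {
        pick(lex$findings_negated[[findings[i]]])
      } else {
        pick(lex$findings[[findings[i]]])
      }
      text[i] <- paste(ind_sentence, pick(lex$technique),
                       pick(lex$comparison), find_sentence)
    }
    doc_id <- sprintf("R%05d", seq_len(total))
    docs <- data.frame(doc_id = doc_id, patient_id = patient,
                       report_date = format(dates, "%Y-%m-%d"),
                       title = title, text = text, stringsAsFactors = FALSE)
    gold <- data.frame(doc_id = doc_id, source = "gold",
                       image_type = image, indication = indication,
                       findings = findings, stringsAsFactors = FALSE)
    corpus <- report_corpus(docs, gold)
    attr(corpus, "provenance") <- data.frame(
      doc_id = doc_id, title_noise = title_noise,
      indication_noise = ind_noise, findings_noise = find_noise,
      negated = negated, stringsAsFactors = FALSE)
    attr(corpus, "config") <- config
    corpus
  })
}

# (axis, positive label) -> text rewrites used by inject_errors(): `hide`
# makes a detected report invisible to the rules (false negative), `plant`
# adds a trigger so an undetected report fires (false positive).
injection_rewrites <- function(axis, positive_label) {
  lex <- report_lexicon()
  key <- paste(axis, positive_label, sep = "/")
  switch(key,
    "image_type/relevant" = list(
      hide = function(title, text) {
        list(title = "RADIOLOGY EXAMINATION OUTSIDE PROTOCOL", text = text)
      },
      plant = function(title, text) {
        list(title = title,
             text = paste(text,
                          "COMPARISON: Correlation with prior chest radiograph."))
      }),
    "indication/surveillance" = list(
      hide = function(title, text) {
        list(title = title,
             text = gsub("surveillance", "interval assessment", text,
                         ignore.case = TRUE))
      },
      plant = function(title, text) {
        list(title = title,
             text = paste(text,
                          "COMPARISON: Prior surveillance examination reviewed."))
      }),
    "findings/suspicious" = list(
      hide = function(title, text) {
        list(title = title,
             text = gsub("suspicious|worrisome|concerning", "ominous", text,
                         ignore.case = TRUE))
      },
      plant = function(title, text) {
        list(title = title,
             text = paste(text,
                          "ADDENDUM: Interval change concerning for recurrence."))
      }),
    "findings/recurrence" = list(
      hide = function(title, text) {
        list(title = title,
             text = gsub("consistent|definite|definitive|diagnostic|compatible",
                         "felt", text, ignore.case = TRUE))
      },
      plant = function(title, text) {
        list(title = title,
             text = paste(text,
                          "ADDENDUM: Findings definite for recurrent disease."))
      }),
    stop(sprintf("no injection rewrites defined for %s", key), call. = FALSE))
}

#' Perturb report text to hit a target operating point
#'
#' Rewrites a computed number of rule-detected positive reports into
#' out-of-lexicon paraphrases (manufacturing false negatives) and plants
#' trigger phrases into a computed number of negative reports
#' (manufacturing false positives) so that the default rules' expected
#' sensitivity and PPV equal the requested targets. Only document text is
#' changed; gold annotations are never touched. Deterministic given the
#' seed.
#'
#' @param corpus a `report_corpus` with gold annotations (typically
#'   generated with `phrase_noise = 0`).
#' @param target_sensitivity,target_ppv targets in (0, 1].
#' @param axis annotation axis of the positive class.
#' @param positive_label label treated as positive; for `axis =
#'   "image_type"` the special value `"relevant"` means "any non-null
#'   image type", matching the relevance pre-filter.
#' @param seed RNG seed for selecting which reports to rewrite.
#' @param rules rule set used to determine current detection status
#'   (default: the shipped rules for `axis`).
#' @return the perturbed `report_corpus`.
#' @export
inject_errors <- function(corpus, target_sensitivity, target_ppv,
                          axis = c("image_type", "indication", "findings"),
                          positive_label = "relevant", seed = 1L,
                          rules = default_rules(axis)) {
  axis <- match.arg(axis)
  stopifnot(target_sensitivity > 0, target_sensitivity <= 1,
            target_ppv > 0, target_ppv <= 1)
  gold <- annotations(corpus, "gold")
  if (!nrow(gold)) stop("corpus has no gold annotations", call. = FALSE)
  if (axis == "image_type" && positive_label == "relevant") {
    pos_ids <- gold$doc_id[gold$image_type != "null"]
  } else {
    if (!positive_label %in% axis_labels(axis)) {
      stop("unknown positive label: ", positive_label, call. = FALSE)
    }
    pos_ids <- gold$doc_id[gold[[axis]] == positive_label]
  }
  neg_ids <- setdiff(gold$doc_id, pos_ids)
  index <- build_index(corpus)
  detected <- if (axis == "image_type" && positive_label == "relevant") {
    classify_relevance(corpus, rules, index = index)
  } else {
    execute_query(index, rules$rules[[positive_label]])$doc_ids
  }
  n_pos <- length(pos_ids)
  tp_target <- round(target_sensitivity * n_pos)
  fp_target <- round(tp_target * (1 - target_ppv) / target_ppv)
  if (fp_target > length(neg_ids)) {
    stop(sprintf(paste0("infeasible targets: PPV %.2f at sensitivity %.2f ",
                        "needs %d false positives but only %d negative ",
                        "reports exist"),
                 target_ppv, target_sensitivity, fp_target, length(neg_ids)),
         call. = FALSE)
  }
  det_pos <- intersect(detected, pos_ids)
  det_neg <- intersect(detected, neg_ids)
  rw <- injection_rewrites(axis, positive_label)
  with_seed(seed, {
    hide_ids <- character(); plant_ids <- character()
    if (length(det_pos) > tp_target) {
      hide_ids <- sample(det_pos, length(det_pos) - tp_target)
    } else if (length(det_pos) < tp_target) {
      undet <- setdiff(pos_ids, det_pos)
      if (tp_target - length(det_pos) > length(undet)) {
        stop("infeasible sensitivity target: not enough positive reports",
             call. = FALSE)
      }
      plant_ids <- sample(undet, tp_target - length(det_pos))
    }
    plant_neg <- character(); hide_neg <- character()
    if (length(det_neg) > fp_target) {
      hide_neg <- sample(det_neg, length(det_neg) - fp_target)
    } else if (length(det_neg) < fp_target) {
      pool <- setdiff(neg_ids, det_neg)
      plant_neg <- sample(pool, fp_target - length(det_neg))
    }
    docs <- corpus$documents
    apply_rewrite <- function(ids, fun) {
      for (id in ids) {
        i <- match(id, docs$doc_id)
        out <- fun(docs$title[i], docs$text[i])
        docs$title[i] <<- out$title
        docs$text[i] <<- out$text
      }
    }
    apply_rewrite(c(hide_ids, hide_neg), rw$hide)
    apply_rewrite(c(plant_ids, plant_neg), rw$plant)
    out <- report_corpus(docs, corpus$annotations)
    attr(out, "injection") <- list(
      axis = axis, positive_label = positive_label,
      target_sensitivity = target_sensitivity, target_ppv = target_ppv,
      hidden = sort(c(hide_ids, hide_neg)),
      planted = sort(c(plant_ids, plant_neg)))
    out
  })
}
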