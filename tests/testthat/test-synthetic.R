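test_that("generation is deterministic given the seed", {
  cfg <- generator_config(n_patients = 25)
  c1 <- generate_corpus(cfg, seed = 42)
  c2 <- generate_corpus(cfg, seed = 42)
  expect_identical(c1$documents, c2$documents)
  expect_identical(c1$annotations, c2$annotations)
  c3 <- generate_corpus(cfg, seed = 43)
  expect_false(identical(c1$documents, c3$documents))
})

test_that("generated marginals match the configured cohort mixes", {
  cfg <- generator_config()  # defaults: 361 patients, cohort mixes
  corp <- generate_corpus(cfg, seed = 2001)
  gold <- annotations(corp, "gold")
  total <- nrow(gold)
  # corpus size near the 3,191-report cohort (3 SDs of the count total)
  expect_lt(abs(total - 3191), 3 * sqrt(361) * 4.4 + 60)
  # each image-type marginal within 3 binomial SEs of its mix probability
  for (lbl in names(cfg$image_type_mix)) {
    p <- cfg$image_type_mix[[lbl]]
    se <- sqrt(p * (1 - p) / total)
    expect_lt(abs(mean(gold$image_type == lbl) - p), 3 * se + 1e-9,
              label = lbl)
  }
  ann <- gold[gold$image_type != "null", ]
  p_surv <- cfg$indication_mix[["surveillance"]]
  expect_lt(abs(mean(ann$indication == "surveillance") - p_surv),
            3 * sqrt(p_surv * (1 - p_surv) / nrow(ann)))
  p_susp <- cfg$findings_mix[["suspicious"]]
  expect_lt(abs(mean(ann$findings == "suspicious") - p_susp),
            3 * sqrt(p_susp * (1 - p_susp) / nrow(ann)))
  # every document is labelled on all three axes
  expect_equal(nrow(gold), n_documents(corp))
  expect_false(anyNA(gold[c("image_type", "indication", "findings")]))
})

test_that("every negated findings mention is invisible to the span rules", {
  cfg <- generator_config(n_patients = 60, negation_rate = 1,
                          phrase_noise = 0)
  corp <- generate_corpus(cfg, seed = 6)
  prov <- attr(corp, "provenance")
  negated_ids <- prov$doc_id[prov$negated]
  expect_gt(length(negated_ids), 20)
  idx <- build_index(corp)
  fr <- default_rules("findings")
  for (lbl in c("suspicious", "recurrence")) {
    hit <- execute_query(idx, fr$rules[[lbl]])$doc_ids
    expect_length(intersect(hit, negated_ids), 0)
  }
})

test_that("phrase noise creates rule-invisible reports at the set rate", {
  cfg <- generator_config(n_patients = 100, phrase_noise = 0.5,
                          negation_rate = 0)
  corp <- generate_corpus(cfg, seed = 9)
  prov <- attr(corp, "provenance")
  gold <- annotations(corp, "gold")
  flagged <- classify_relevance(corp)
  noisy <- prov$doc_id[prov$title_noise]
  expect_length(intersect(flagged, noisy), 0)
  clean_relevant <- setdiff(gold$doc_id[gold$image_type != "null"], noisy)
  expect_setequal(flagged, clean_relevant)
})

test_that("inject_errors with unit targets is the identity on a clean corpus", {
  cfg <- generator_config(n_patients = 30, phrase_noise = 0,
                          negation_rate = 0)
  corp <- generate_corpus(cfg, seed = 4)
  out <- inject_errors(corp, 1.0, 1.0, axis = "image_type",
                       positive_label = "relevant", seed = 1)
  expect_identical(out$documents, corp$documents)
})

test_that("inject_errors is deterministic and never touches gold labels", {
  cfg <- generator_config(n_patients = 40, phrase_noise = 0,
                          negation_rate = 0)
  corp <- generate_corpus(cfg, seed = 5)
  a <- inject_errors(corp, 0.8, 0.98, axis = "image_type",
                     positive_label = "relevant", seed = 7)
  b <- inject_errors(corp, 0.8, 0.98, axis = "image_type",
                     positive_label = "relevant", seed = 7)
  expect_identical(a$documents, b$documents)
  expect_identical(annotations(a, "gold"), annotations(corp, "gold"))
  expect_identical(a$documents$doc_id, corpus_ids <- corp$documents$doc_id)
  expect_identical(a$documents$report_date, corp$documents$report_date)
})

test_that("inject_errors hits a requested findings operating point", {
  cfg <- generator_config(n_patients = 120, phrase_noise = 0,
                          negation_rate = 0)
  corp <- generate_corpus(cfg, seed = 8)
  inj <- inject_errors(corp, 0.75, 0.25, axis = "findings",
                       positive_label = "suspicious", seed = 2)
  gold <- annotations(inj, "gold")
  hit <- execute_query(build_index(inj),
                       default_rules("findings")$rules[["suspicious"]])$doc_ids
  gv <- stats::setNames(gold$findings, gold$doc_id)
  pv <- stats::setNames(ifelse(gold$doc_id %in% hit, "suspicious", "null"),
                        gold$doc_id)
  m <- metrics(confusion(gv, pv, positive = "suspicious"))
  expect_lt(abs(m$sensitivity - 0.75), 0.03)
  expect_lt(abs(m$ppv - 0.25), 0.03)
})

test_that("infeasible injection targets fail with the binding constraint", {
  cfg <- generator_config(n_patients = 20, phrase_noise = 0,
                          negation_rate = 0)
  corp <- generate_corpus(cfg, seed = 3)
  # PPV so low it would need more false positives than negatives exist
  expect_error(inject_errors(corp, 1.0, 0.02, axis = "image_type",
                             positive_label = "relevant", seed = 1),
               "infeasible")
})

test_that("generator config validates its probability mixes", {
  bad_mix <- table1_image_mix_local <- c(bone_scan = 0.5, chest_xray = 0.6)
  expect_error(generator_config(image_type_mix = bad_mix),
               "probability vector")
  mix <- generator_config()$image_type_mix
  expect_equal(sum(mix), 1, tolerance = 1e-9)
  mix[1] <- mix[1] + 0.1
  expect_error(generator_config(image_type_mix = mix), "sum to 1")
})
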