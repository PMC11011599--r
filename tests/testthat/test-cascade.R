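test_that("rules decide first; SVM covers every abstention", {
  lib <- default_pattern_library()
  model <- shared_model()
  s <- rbind(
    make_snippet("former opioid dependence", "opioid dependence", 1L),
    make_snippet("escalating use of oxycodone obtained from multiple providers raising concern for misuse",
                 "oxycodone", 3L),
    make_snippet("patient requested no lortab", "lortab", 3L))
  cl <- classify_snippets(s, lib, model)
  expect_equal(nrow(cl), nrow(s))           # coverage
  expect_false(any(cl$label == "abstain"))
  expect_equal(cl$label[1], "negative")
  expect_equal(cl$method[1], "rule")
  expect_equal(cl$tier[1], "canceling")
  expect_equal(cl$method[2:3], c("svm", "svm"))
  expect_equal(cl$tier[2:3], c("", ""))
  # method = rule iff tier non-empty
  expect_equal(cl$method == "rule", nzchar(cl$tier))
})

test_that("cascade without a model errors only when rules abstain", {
  lib <- default_pattern_library()
  decided <- make_snippet("former opioid dependence", "opioid dependence", 1L)
  expect_silent(classify_snippets(decided, lib, model = NULL))
  open <- make_snippet("pt doing well today", "opioid")
  expect_error(classify_snippets(open, lib, model = NULL), "no text model")
})

test_that("cascade is deterministic and empty input yields empty output", {
  lib <- default_pattern_library()
  model <- shared_model()
  gold <- shared_corpus()$gold[1:50, ]
  expect_identical(classify_snippets(gold, lib, model),
                   classify_snippets(gold, lib, model))
  e <- classify_snippets(gold[0, ], lib, model)
  expect_equal(nrow(e), 0L)
  expect_true(all(c("label", "method", "tier") %in% names(e)))
})

test_that("document summary counts positive notes by the >=1 rule", {
  cl <- make_classified(c("p1", "p1", "p2", "p3"),
                        c("positive", "negative", "negative", "positive"))
  cl$note_id <- c("n1", "n1", "n2", "n3")
  s <- classification_summary(cl)
  expect_equal(s$n_notes, 3L)
  expect_equal(s$n_snippets, 4L)
  expect_equal(s$n_positive_snippets, 2L)
  expect_equal(s$n_positive_notes, 2L)
  expect_equal(s$mean_snippets_per_note, 4 / 3)
})

test_that("ICD positivity uses the exact ICD-9 codes and the F11 family", {
  expect_true(is_icd_positive("304.00"))
  expect_true(is_icd_positive("F11.20"))
  expect_true(is_icd_positive(c("I10", "f11.90")))   # case-normalized
  expect_false(is_icd_positive(c("F10.20", "305.1")))
  expect_false(is_icd_positive("304.01"))
  expect_false(is_icd_positive(character()))
})

test_that("group assignment partitions the cohort and flags the overlap", {
  patients <- data.frame(patient_id = c("p1", "p2", "p3"))
  cl <- make_classified(c("p1", "p1", "p2"),
                        c("positive", "positive", "positive"))
  icd <- data.frame(patient_id = "p1", code = "304.00", date = "2015-01-01")
  ga <- assign_groups(patients, cl, icd)
  expect_equal(as.character(ga$group),
               c("ALL_ICD", "NLP_ONLY", "NO_PROBLEMATIC_USE"))
  gc <- group_counts(ga)
  expect_equal(unname(gc["overlap"]), 1L)
  expect_equal(unname(gc["all_icd"] + gc["nlp_only"] +
                        gc["no_problematic_use"]), unname(gc["n"]))
  expect_equal(unname(gc["overlap"]),
               unname(gc["nlp_positive"] - gc["nlp_only"]))
  # orphan snippets are an error naming the unknown ids
  orphan <- make_classified("p9", "positive")
  expect_error(assign_groups(patients, orphan, icd), "p9")
})

test_that("index date is the earliest documentation, ICD winning ties", {
  notes <- data.frame(note_id = c("n1", "n2"),
                      note_date = c("2014-05-01", "2016-01-01"))
  cl <- make_classified(c("p1", "p2"), c("positive", "positive"))
  cl$note_id <- c("n1", "n2")
  icd <- data.frame(patient_id = c("p1", "p2"),
                    code = c("F11.20", "304.00"),
                    date = c("2015-03-01", "2016-01-01"))
  idx <- compute_index_dates(icd, cl, notes)
  expect_equal(idx$index_date[idx$patient_id == "p1"], as.Date("2014-05-01"))
  expect_equal(idx$source[idx$patient_id == "p1"], "nlp")
  # same-day tie resolves to the ICD source
  expect_equal(idx$source[idx$patient_id == "p2"], "icd")
})

test_that("positive-pattern tallies split drug names from concept phrases", {
  lex <- tiny_lexicon()
  cl <- rbind(make_classified("p1", "positive"),
              make_classified("p1", "positive"),
              make_classified("p2", "positive"))
  cl$key_phrase <- c("oxycodone", "withdrawal", "withdrawal")
  patients <- data.frame(patient_id = c("p1", "p2", "p3"))
  icd <- data.frame(patient_id = "p2", code = "F11.20", date = "2015-01-01")
  ga <- assign_groups(patients, cl, icd)
  tl <- tally_positive_patterns(cl, lex, ga)
  nlp_only <- tl[tl$group == "NLP_ONLY", ]
  # p1 appears in both count columns; mean positives per patient = 2
  expect_equal(nlp_only$n_drug_name_patients, 1L)
  expect_equal(nlp_only$n_other_patients, 1L)
  expect_equal(nlp_only$mean_positive_snippets, 2)
  overlap <- tl[tl$group == "NLP_ICD", ]
  expect_equal(overlap$n_drug_name_patients, 0L)
  expect_equal(overlap$n_other_patients, 1L)
  # a group with no positives yields a zero row
  none <- tally_positive_patterns(cl[0, ], lex, ga, groups = "NLP_ONLY")
  expect_equal(none$n_drug_name_patients, 0L)
  expect_equal(none$mean_positive_snippets, 0)
})
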